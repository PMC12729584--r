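#' Feature-construction GA configuration
#'
#' Parameters of the genetic algorithm that evolves integer chromosomes
#' whose grammatical-evolution mapping yields `n_features` symbolic
#' expressions minimising the training sum of squared errors of an RBF
#' network on the transformed data.
#'
#' @param generations Maximum generations (default 500).
#' @param population Chromosome count (default 500).
#' @param selection_rate Fraction of the population replaced by
#'   offspring each generation (default 0.10); the best
#'   `(1 - selection_rate) * population` chromosomes are copied intact.
#' @param mutation_rate Per-codon mutation probability for offspring
#'   (default 0.05); a mutated codon is redrawn uniformly.
#' @param n_features Number of constructed features, typically 2-4
#'   (default 3).
#' @param chromosome_length Codons per chromosome (default 100).
#' @param codon_bound Maximum codon value (default 255).
#' @param tournament_size Tournament size for parent selection
#'   (default 4).
#' @param rbf_nodes Hidden nodes of the fitness RBF network
#'   (default 10).
#' @param max_wraps Wrap budget per mapped expression (default 2).
#' @param penalty_fitness Fitness assigned to invalid chromosomes
#'   (default 1e100; finite so sorting stays total).
#' @param seed Integer seed.
#' @return An object of class `fc_config`.
#' @export
fc_config <- function(generations = 500L, population = 500L,
                      selection_rate = 0.10, mutation_rate = 0.05,
                      n_features = 3L, chromosome_length = 100L,
                      codon_bound = 255L, tournament_size = 4L,
                      rbf_nodes = 10L, max_wraps = 2L,
                      penalty_fitness = 1e100, seed = 1L) {
  if (selection_rate <= 0 || selection_rate >= 1) {
    stop("selection_rate must be in (0, 1)")
  }
  if (mutation_rate < 0 || mutation_rate > 1) {
    stop("mutation_rate must be in [0, 1]")
  }
  if (n_features < 1L) stop("n_features must be >= 1")
  if (generations < 1L || population < 2L) {
    stop("need generations >= 1 and population >= 2")
  }
  structure(list(generations = as.integer(generations),
                 population = as.integer(population),
                 selection_rate = selection_rate,
                 mutation_rate = mutation_rate,
                 n_features = as.integer(n_features),
                 chromosome_length = as.integer(chromosome_length),
                 codon_bound = as.integer(codon_bound),
                 tournament_size = as.integer(tournament_size),
                 rbf_nodes = as.integer(rbf_nodes),
                 max_wraps = as.integer(max_wraps),
                 penalty_fitness = penalty_fitness,
                 seed = as.integer(seed)),
            class = "fc_config")
}

#' Initialize a random chromosome population
#'
#' @param cfg An [fc_config()].
#' @return Integer matrix, `population` rows x `chromosome_length`
#'   columns, codons uniform on `[0, codon_bound]`.
#' @export
initialize_population <- function(cfg) {
  with_local_seed(cfg$seed, {
    matrix(sample.int(cfg$codon_bound + 1L,
                      cfg$population * cfg$chromosome_length,
                      replace = TRUE) - 1L,
           nrow = cfg$population, ncol = cfg$chromosome_length)
  })
}

#' Map a chromosome to a set of constructed-feature expressions
#'
#' The `n_features` expressions are mapped sequentially from a single
#' codon stream: expression `i + 1` resumes at the codon where
#' expression `i` stopped, with the usual wrap policy per expression.
#' If any mapping fails the whole set is invalid.
#'
#' @param codons Integer vector (one chromosome).
#' @param cfg An [fc_config()].
#' @param grammar A `bnf_grammar` whose dimension matches the original
#'   feature count.
#' @return List with `valid` and, when valid, `expressions` (list of
#'   `ge_expr`).
#' @export
build_feature_set <- function(codons, cfg, grammar) {
  chrom <- chromosome(codons, bounds = cfg$codon_bound)
  idx <- 1L
  exprs <- vector("list", cfg$n_features)
  for (i in seq_len(cfg$n_features)) {
    mp <- map_chromosome(chrom, grammar, max_wraps = cfg$max_wraps,
                         start_index = idx)
    if (!mp$valid) return(list(valid = FALSE, expressions = NULL))
    exprs[[i]] <- mp$expression
    idx <- mp$next_index
    if (idx > length(codons)) idx <- 1L
  }
  list(valid = TRUE, expressions = exprs)
}

#' Train an RBF network
#'
#' Centers are placed by (seeded) k-means, the width of each Gaussian
#' unit is the mean distance of its cluster members to the center
#' (floored at 1e-6), and the linear output weights (plus bias) are the
#' ridge-stabilised least-squares solution (ridge 1e-8). When fewer
#' patterns than nodes are supplied, the node count is reduced to the
#' pattern count.
#'
#' @param X Numeric matrix of patterns (rows).
#' @param t Numeric target vector.
#' @param k Number of hidden nodes (default 10).
#' @param seed Integer seed for the k-means initialisation.
#' @return An object of class `rbf_model`.
#' @export
train_rbf <- function(X, t, k = 10L, seed = 1L) {
  X <- as.matrix(X)
  M <- nrow(X)
  stopifnot(M >= 1L, length(t) == M)
  if (M < k) {
    gefc_log("reducing RBF nodes from %d to %d patterns", k, M)
    k <- M
  }
  uniq <- nrow(unique(X))
  k <- min(k, uniq)
  centers <- with_local_seed(seed, {
    if (k == 1L) {
      matrix(colMeans(X), nrow = 1L)
    } else if (k >= uniq) {
      unique(X)  # one center per distinct pattern: interpolation
    } else {
      km <- suppressWarnings(
        stats::kmeans(X, centers = k, iter.max = 50L, nstart = 1L))
      km$centers
    }
  })
  # assign each pattern to its nearest center for the width estimate
  d2 <- outer(rowSums(X^2), rep(1, k)) - 2 * X %*% t(centers) +
    outer(rep(1, M), rowSums(centers^2))
  d2[d2 < 0] <- 0
  assign <- max.col(-d2, ties.method = "first")
  widths <- vapply(seq_len(k), function(j) {
    members <- assign == j
    if (!any(members)) return(1e-6)
    max(mean(sqrt(d2[members, j])), 1e-6)
  }, numeric(1))
  model <- structure(list(centers = centers, widths = widths,
                          weights = NULL),
                     class = "rbf_model")
  Phi <- rbf_design(model, X)
  A <- crossprod(Phi) + diag(1e-8, ncol(Phi))
  model$weights <- as.numeric(solve(A, crossprod(Phi, t)))
  model
}

rbf_design <- function(model, X) {
  X <- as.matrix(X)
  k <- nrow(model$centers)
  d2 <- outer(rowSums(X^2), rep(1, k)) - 2 * X %*% t(model$centers) +
    outer(rep(1, nrow(X)), rowSums(model$centers^2))
  d2[d2 < 0] <- 0
  Phi <- exp(-sweep(d2, 2, 2 * model$widths^2, "/"))
  cbind(1, Phi)
}

#' @export
predict.rbf_model <- function(object, newdata, ...) {
  as.numeric(rbf_design(object, newdata) %*% object$weights)
}

#' Fitness of a chromosome on a training set
#'
#' The patterns are transformed through the chromosome's constructed
#' features and an RBF network is trained on the transformed set; the
#' fitness is the training sum of squared errors
#' `sum((C(x_hat_j) - t_j)^2)`. An invalid mapping, or any non-finite
#' transformed value, earns `penalty_fitness`.
#'
#' @param codons Integer chromosome.
#' @param X Numeric matrix of original patterns.
#' @param t Numeric targets (class labels).
#' @param cfg An [fc_config()].
#' @param grammar A `bnf_grammar`.
#' @return Scalar fitness (lower is better).
#' @export
fc_fitness <- function(codons, X, t, cfg, grammar) {
  fs <- build_feature_set(codons, cfg, grammar)
  if (!fs$valid) return(cfg$penalty_fitness)
  Z <- transform_patterns(fs$expressions, X)
  if (anyNA(Z)) return(cfg$penalty_fitness)
  model <- train_rbf(Z, t, k = cfg$rbf_nodes,
                     seed = derive_seed(cfg$seed, "rbf"))
  pred <- predict(model, Z)
  sum((pred - t)^2)
}

transform_patterns <- function(expressions, X) {
  Xm <- as.matrix(X)
  Z <- vapply(expressions, function(e) evaluate_expression_matrix(e, Xm),
              numeric(nrow(Xm)))
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1L)
  Z
}

#' Evolve constructed features
#'
#' Genetic algorithm over integer chromosomes: each generation the
#' population is sorted by fitness, the best
#' `(1 - selection_rate) * population` chromosomes are copied intact,
#' and the remainder is replaced by offspring bred by tournament
#' selection and one-point crossover (cut position uniform in
#' `[1, length - 1]`), with per-codon uniform-redraw mutation. Elitism
#' makes the best-ever fitness non-increasing.
#'
#' @param X Numeric matrix of training patterns (original features).
#' @param t Numeric targets.
#' @param cfg An [fc_config()].
#' @param grammar A `bnf_grammar` built with `d = ncol(X)`; built
#'   automatically when omitted.
#' @return An object of class `constructed_features`: `expressions`
#'   (list of `ge_expr`), `strings`, `best_fitness`, `fitness_trace`
#'   (per-generation best), `mean_trace`, `best_chromosome`, `config`.
#' @export
evolve_features <- function(X, t, cfg = fc_config(), grammar = NULL) {
  X <- as.matrix(X)
  if (is.null(grammar)) grammar <- default_feature_grammar(ncol(X))
  if (grammar$d != ncol(X)) {
    stop("grammar dimension ", grammar$d, " does not match ncol(X) = ",
         ncol(X))
  }
  pop <- initialize_population(cfg)
  Nc <- cfg$population
  len <- cfg$chromosome_length
  n_off <- max(2L, round(cfg$selection_rate * Nc))
  if (n_off %% 2L == 1L) n_off <- n_off + 1L
  n_elite <- Nc - n_off

  eval_fit <- function(ch) fc_fitness(ch, X, t, cfg, grammar)
  fit <- apply(pop, 1, eval_fit)
  trace_best <- numeric(cfg$generations)
  trace_mean <- numeric(cfg$generations)

  with_local_seed(derive_seed(cfg$seed, "construct"), {
    for (gen in seq_len(cfg$generations)) {
      ord <- order(fit)
      pop <- pop[ord, , drop = FALSE]
      fit <- fit[ord]
      offspring <- matrix(0L, n_off, len)
      for (pair in seq_len(n_off / 2L)) {
        p1 <- tournament_pick(fit, cfg$tournament_size)
        p2 <- tournament_pick(fit, cfg$tournament_size)
        cut <- sample.int(len - 1L, 1L)
        offspring[2L * pair - 1L, ] <- c(pop[p1, 1:cut],
                                         pop[p2, (cut + 1L):len])
        offspring[2L * pair, ] <- c(pop[p2, 1:cut],
                                    pop[p1, (cut + 1L):len])
      }
      mut <- matrix(stats::runif(n_off * len) <= cfg$mutation_rate,
                    n_off, len)
      if (any(mut)) {
        offspring[mut] <- sample.int(cfg$codon_bound + 1L, sum(mut),
                                     replace = TRUE) - 1L
      }
      off_fit <- apply(offspring, 1, eval_fit)
      pop[(n_elite + 1L):Nc, ] <- offspring
      fit[(n_elite + 1L):Nc] <- off_fit
      trace_best[gen] <- min(fit)
      finite_fit <- fit[fit < cfg$penalty_fitness]
      trace_mean[gen] <- if (length(finite_fit)) mean(finite_fit) else
        cfg$penalty_fitness
    }
  })
  best_i <- which.min(fit)
  best <- pop[best_i, ]
  fs <- build_feature_set(best, cfg, grammar)
  structure(list(expressions = fs$expressions,
                 strings = vapply(fs$expressions, expr_to_string,
                                  character(1)),
                 best_fitness = fit[best_i],
                 fitness_trace = cummin(trace_best),
                 mean_trace = trace_mean,
                 best_chromosome = best,
                 d = ncol(X),
                 config = cfg),
            class = "constructed_features")
}

tournament_pick <- function(fit, size) {
  cand <- sample.int(length(fit), size, replace = FALSE)
  cand[which.min(fit[cand])]
}

#' @export
print.constructed_features <- function(x, ...) {
  cat(sprintf("constructed_features: %d expressions, best fitness %.6g\n",
              length(x$expressions), x$best_fitness))
  for (i in seq_along(x$strings)) {
    cat(sprintf("  gf_%d = %s\n", i, x$strings[i]))
  }
  invisible(x)
}

#' Transform a dataset through constructed features
#'
#' Every row of the original feature matrix is pushed through the
#' evolved expressions, giving columns `gf_1..gf_Nf`; labels and
#' metadata are carried over. Guarded non-finite evaluations are
#' clipped to +/-1e100 and counted.
#'
#' @param fm A [feature_matrix()] whose column count matches the
#'   grammar dimension used to evolve `fs`.
#' @param fs A `constructed_features` object (or list of `ge_expr`).
#' @return A new `feature_matrix` with `Nf` columns; the number of
#'   clipped cells is attached as attribute `"n_clipped"`.
#' @export
transform_dataset <- function(fm, fs) {
  stopifnot(inherits(fm, "feature_matrix"))
  expressions <- if (inherits(fs, "constructed_features")) fs$expressions
                 else fs
  if (inherits(fs, "constructed_features") &&
      ncol(fm$features) != fs$d) {
    stop("feature dimension mismatch: matrix has ", ncol(fm$features),
         " columns but the features were evolved on ", fs$d)
  }
  Z <- transform_patterns(expressions, fm$features)
  n_clipped <- sum(is.na(Z))
  if (n_clipped > 0L) {
    gefc_log("clipped %d non-finite constructed-feature values", n_clipped)
    Z[is.na(Z)] <- 1e100
    Z[Z > 1e100] <- 1e100
    Z[Z < -1e100] <- -1e100
  }
  colnames(Z) <- paste0("gf_", seq_along(expressions))
  out <- feature_matrix(Z, fm$labels, fm$meta, fm$exercise)
  attr(out, "n_clipped") <- n_clipped
  out
}
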