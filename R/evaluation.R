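#' Evaluation configuration
#'
#' @param folds Cross-validation folds (default 10).
#' @param repeats Repetitions of the whole CV (default 30).
#' @param hidden_nodes Hidden/processing nodes of the baseline networks
#'   (default 10).
#' @param pca_components Components for the PCA baseline (default 2).
#' @param group_by_patient Stratify folds by patient so windows of one
#'   patient never span train and test (default FALSE: stratify by
#'   label only).
#' @param seed Integer seed.
#' @return An object of class `eval_config`.
#' @export
eval_config <- function(folds = 10L, repeats = 30L, hidden_nodes = 10L,
                        pca_components = 2L, group_by_patient = FALSE,
                        seed = 1L) {
  if (folds < 2L) stop("folds must be >= 2")
  if (repeats < 1L) stop("repeats must be >= 1")
  structure(list(folds = as.integer(folds), repeats = as.integer(repeats),
                 hidden_nodes = as.integer(hidden_nodes),
                 pca_components = as.integer(pca_components),
                 group_by_patient = isTRUE(group_by_patient),
                 seed = as.integer(seed)),
            class = "eval_config")
}

#' Classification metrics from a confusion matrix
#'
#' Error is `100 * (fp + fn) / total` (percent). Precision and recall
#' are macro-averaged over the two classes (ON = positive class 1); a
#' class with zero denominator contributes 0.
#'
#' @param tp,fp,fn,tn Non-negative integer counts.
#' @return Named numeric vector `error`, `precision`, `recall`.
#' @export
compute_metrics <- function(tp, fp, fn, tn) {
  total <- tp + fp + fn + tn
  if (total <= 0) stop("empty confusion matrix")
  prec_pos <- if (tp + fp > 0) tp / (tp + fp) else 0
  prec_neg <- if (tn + fn > 0) tn / (tn + fn) else 0
  rec_pos <- if (tp + fn > 0) tp / (tp + fn) else 0
  rec_neg <- if (tn + fp > 0) tn / (tn + fp) else 0
  c(error = 100 * (fp + fn) / total,
    precision = (prec_pos + prec_neg) / 2,
    recall = (rec_pos + rec_neg) / 2)
}

# Stratified fold assignment: indices of each stratum are shuffled and
# dealt round-robin with a counter continuing across strata, so fold
# sizes differ by at most one overall and per class.
stratified_folds <- function(labels, k, seed, groups = NULL) {
  n <- length(labels)
  folds <- integer(n)
  with_local_seed(seed, {
    if (is.null(groups)) {
      counter <- 0L
      for (cl in sort(unique(labels))) {
        idx <- which(labels == cl)
        idx <- idx[sample.int(length(idx))]
        folds[idx] <- ((counter + seq_along(idx) - 1L) %% k) + 1L
        counter <- counter + length(idx)
      }
    } else {
      # group-stratified: whole patients are dealt to folds
      gs <- unique(groups)
      gs <- gs[sample.int(length(gs))]
      gf <- stats::setNames(((seq_along(gs) - 1L) %% k) + 1L, gs)
      folds <- gf[as.character(groups)]
    }
  })
  as.integer(folds)
}

#' Baseline and feature-construction classifier specifications
#'
#' Constructors for the model specifications accepted by
#' [crossval_evaluate()]:
#' * `method_rbf()` — RBF network with `hidden_nodes` Gaussian units on
#'   the raw features.
#' * `method_gen_mlp()` — single-hidden-layer sigmoid network whose
#'   weights (in `[-10, 10]`) are evolved by a real-coded genetic
#'   algorithm minimising training SSE.
#' * `method_pca_mlp()` — projection onto the first `pca_components`
#'   principal components followed by a BFGS-trained MLP.
#' * `method_fc()` — grammatical-evolution feature construction on the
#'   training fold (per `fc_cfg`), then an RBF network on the
#'   constructed features; test folds are transformed with the evolved
#'   expressions, so no information leaks from the test fold.
#'
#' Each specification is a list with `name`, `fit(X, y, seed, cfg)` and
#' `predict(model, X)`; predictions are scores in `[0, 1]` thresholded
#' at 0.5.
#'
#' @param fc_cfg An [fc_config()] for `method_fc`.
#' @param ga_generations,ga_population Real-coded GA budget for
#'   `method_gen_mlp`.
#' @return A model specification list.
#' @name model_methods
NULL

#' @rdname model_methods
#' @export
method_rbf <- function() {
  list(name = "rbf",
       fit = function(X, y, seed, cfg) {
         train_rbf(X, y, k = cfg$hidden_nodes, seed = seed)
       },
       predict = function(model, X) predict(model, X))
}

#' @rdname model_methods
#' @export
method_fc <- function(fc_cfg = fc_config()) {
  list(name = sprintf("fc%d", fc_cfg$n_features),
       fit = function(X, y, seed, cfg) {
         cfg_i <- fc_cfg
         cfg_i$seed <- seed
         fs <- evolve_features(X, y, cfg_i)
         Z <- transform_patterns(fs$expressions, X)
         Z[is.na(Z)] <- 1e100
         model <- train_rbf(Z, y, k = fc_cfg$rbf_nodes,
                            seed = derive_seed(seed, "rbf"))
         list(features = fs, rbf = model)
       },
       predict = function(model, X) {
         Z <- transform_patterns(model$features$expressions, X)
         Z[is.na(Z)] <- 1e100
         predict(model$rbf, Z)
       })
}

#' @rdname model_methods
#' @export
method_gen_mlp <- function(ga_generations = 50L, ga_population = 50L) {
  list(name = "gen",
       fit = function(X, y, seed, cfg) {
         train_gen_mlp(X, y, H = cfg$hidden_nodes, seed = seed,
                       generations = ga_generations,
                       population = ga_population)
       },
       predict = function(model, X) mlp_forward(model$weights, X, model$H))
}

#' @rdname model_methods
#' @export
method_pca_mlp <- function() {
  list(name = "pca",
       fit = function(X, y, seed, cfg) {
         sds <- apply(X, 2, stats::sd)
         keep <- which(sds > 0)
         pc <- stats::prcomp(X[, keep, drop = FALSE], center = TRUE,
                             scale. = TRUE)
         ncomp <- min(cfg$pca_components, ncol(pc$rotation))
         Z <- pc$x[, seq_len(ncomp), drop = FALSE]
         net <- with_local_seed(seed, {
           nnet::nnet(Z, y, size = cfg$hidden_nodes, linout = TRUE,
                      maxit = 200, trace = FALSE)
         })
         list(pc = pc, keep = keep, ncomp = ncomp, net = net)
       },
       predict = function(model, X) {
         Z <- predict(model$pc,
                      X[, model$keep, drop = FALSE])[, seq_len(model$ncomp),
                                                     drop = FALSE]
         as.numeric(predict(model$net, Z))
       })
}

# forward pass of a 1-hidden-layer sigmoid MLP with linear output;
# weights packed as [W1 (d+1 x H), w2 (H+1)]
mlp_forward <- function(w, X, H) {
  X <- as.matrix(X)
  d <- ncol(X)
  W1 <- matrix(w[seq_len((d + 1L) * H)], d + 1L, H)
  w2 <- w[((d + 1L) * H + 1L):((d + 1L) * H + H + 1L)]
  A <- cbind(1, X) %*% W1
  Hid <- 1 / (1 + exp(-A))
  as.numeric(cbind(1, Hid) %*% w2)
}

# real-coded GA (genes in [-10, 10]) minimising training SSE of the MLP
train_gen_mlp <- function(X, y, H = 10L, seed = 1L, generations = 50L,
                          population = 50L, selection_rate = 0.1,
                          mutation_rate = 0.05) {
  X <- as.matrix(X)
  nw <- (ncol(X) + 1L) * H + H + 1L
  sse <- function(w) {
    p <- mlp_forward(w, X, H)
    if (any(!is.finite(p))) return(1e100)
    sum((p - y)^2)
  }
  with_local_seed(seed, {
    pop <- matrix(stats::runif(population * nw, -10, 10), population, nw)
    fit <- apply(pop, 1, sse)
    n_off <- max(2L, round(selection_rate * population))
    if (n_off %% 2L == 1L) n_off <- n_off + 1L
    n_elite <- population - n_off
    trace <- numeric(generations)
    for (gen in seq_len(generations)) {
      ord <- order(fit)
      pop <- pop[ord, , drop = FALSE]
      fit <- fit[ord]
      off <- matrix(0, n_off, nw)
      for (pair in seq_len(n_off / 2L)) {
        p1 <- tournament_pick(fit, 4L)
        p2 <- tournament_pick(fit, 4L)
        cut <- sample.int(nw - 1L, 1L)
        off[2L * pair - 1L, ] <- c(pop[p1, 1:cut], pop[p2, (cut + 1L):nw])
        off[2L * pair, ] <- c(pop[p2, 1:cut], pop[p1, (cut + 1L):nw])
      }
      mut <- matrix(stats::runif(n_off * nw) <= mutation_rate, n_off, nw)
      off[mut] <- stats::runif(sum(mut), -10, 10)
      off_fit <- apply(off, 1, sse)
      pop[(n_elite + 1L):population, ] <- off
      fit[(n_elite + 1L):population] <- off_fit
      trace[gen] <- min(fit)
    }
    best <- which.min(fit)
    list(weights = pop[best, ], H = H, fitness_trace = cummin(trace))
  })
}

#' Train a baseline classifier on a feature matrix
#'
#' @param fm A [feature_matrix()].
#' @param kind One of `"rbf"`, `"gen_mlp"`, `"pca_mlp"`.
#' @param cfg An [eval_config()].
#' @return The fitted model (class depends on `kind`).
#' @export
train_baseline <- function(fm, kind = c("rbf", "gen_mlp", "pca_mlp"),
                           cfg = eval_config()) {
  kind <- match.arg(kind)
  spec <- switch(kind, rbf = method_rbf(), gen_mlp = method_gen_mlp(),
                 pca_mlp = method_pca_mlp())
  spec$fit(fm$features, fm$labels, cfg$seed, cfg)
}

#' Repeated stratified cross-validation of a model specification
#'
#' For every repeat a stratified `folds`-fold partition is drawn from a
#' repeat-indexed seed; the model is fitted on the training folds and
#' scored on the held-out fold. Any fitted feature construction or
#' projection is learned on the training folds only. Metrics are
#' averaged over folds and repeats; ROC/PR points are pooled from the
#' final repeat's held-out scores.
#'
#' @param fm A [feature_matrix()].
#' @param method A specification from [model_methods].
#' @param cfg An [eval_config()].
#' @return An `evaluation_report`: list with `method`, `error`,
#'   `precision`, `recall`, `per_fold` (data.frame), `roc`, `pr`,
#'   `auroc`, `aupr`, `config`.
#' @export
crossval_evaluate <- function(fm, method, cfg = eval_config()) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (length(unique(fm$labels)) < 2L) stop("both classes must be present")
  per_fold <- list()
  pooled_scores <- NULL
  pooled_labels <- NULL
  for (rep_i in seq_len(cfg$repeats)) {
    groups <- if (cfg$group_by_patient) fm$meta$patient_id else NULL
    fold_id <- stratified_folds(fm$labels, cfg$folds,
                                seed = derive_seed(cfg$seed + rep_i, "fold"),
                                groups = groups)
    for (f in sort(unique(fold_id))) {
      test <- fold_id == f
      if (length(unique(fm$labels[!test])) < 2L) next
      model <- method$fit(fm$features[!test, , drop = FALSE],
                          fm$labels[!test],
                          derive_seed(cfg$seed + rep_i, "evaluate") + f,
                          cfg)
      scores <- method$predict(model, fm$features[test, , drop = FALSE])
      pred <- as.integer(scores >= 0.5)
      truth <- fm$labels[test]
      m <- compute_metrics(tp = sum(pred == 1L & truth == 1L),
                           fp = sum(pred == 1L & truth == 0L),
                           fn = sum(pred == 0L & truth == 1L),
                           tn = sum(pred == 0L & truth == 0L))
      per_fold[[length(per_fold) + 1L]] <-
        data.frame(repeat_i = rep_i, fold = f, error = m["error"],
                   precision = m["precision"], recall = m["recall"])
      if (rep_i == cfg$repeats) {
        pooled_scores <- c(pooled_scores, scores)
        pooled_labels <- c(pooled_labels, truth)
      }
    }
  }
  per_fold <- do.call(rbind, per_fold)
  rownames(per_fold) <- NULL
  curves <- roc_pr_points(pooled_scores, pooled_labels)
  structure(list(method = method$name,
                 error = mean(per_fold$error),
                 precision = mean(per_fold$precision),
                 recall = mean(per_fold$recall),
                 per_fold = per_fold,
                 roc = curves$roc, pr = curves$pr,
                 auroc = curves$auroc, aupr = curves$aupr,
                 config = cfg),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "evaluation_report [%s]: error %.2f%%, precision %.3f, recall %.3f (AUROC %.3f)\n",
    x$method, x$error, x$precision, x$recall, x$auroc))
  invisible(x)
}

#' ROC and precision-recall points
#'
#' Threshold sweep over the unique scores (predict positive when
#' `score >= threshold`): ROC points are (FPR, TPR) and PR points are
#' (recall, precision); both areas are computed by the trapezoid rule.
#'
#' @param scores Numeric classifier scores (larger = more positive).
#' @param labels Binary 0/1 labels.
#' @return List with data.frames `roc` (fpr, tpr), `pr` (recall,
#'   precision) and scalars `auroc`, `aupr`.
#' @export
roc_pr_points <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present for ROC/PR curves")
  }
  npos <- sum(labels == 1L)
  nneg <- sum(labels == 0L)
  thresholds <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- fpr <- prec <- numeric(length(thresholds))
  for (i in seq_along(thresholds)) {
    pred <- scores >= thresholds[i]
    tp <- sum(pred & labels == 1L)
    fp <- sum(pred & labels == 0L)
    tpr[i] <- tp / npos
    fpr[i] <- fp / nneg
    prec[i] <- if (tp + fp > 0) tp / (tp + fp) else 1
  }
  auroc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  aupr <- sum(diff(tpr) * (head(prec, -1) + prec[-1]) / 2)
  list(roc = data.frame(fpr = fpr, tpr = tpr),
       pr = data.frame(recall = tpr, precision = prec),
       auroc = auroc, aupr = aupr)
}
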