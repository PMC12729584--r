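test_that("population initialization is reproducible and in bounds", {
  cfg <- fc_config(population = 500L, seed = 42L)
  pop <- initialize_population(cfg)
  expect_equal(dim(pop), c(500L, 100L))
  expect_true(all(pop >= 0L & pop <= 255L))
  expect_identical(pop, initialize_population(cfg))
  pop2 <- initialize_population(fc_config(population = 500L, seed = 43L))
  expect_false(identical(pop, pop2))
})

test_that("feature sets map sequentially from one codon stream", {
  g <- default_feature_grammar(3)
  cfg <- fc_config(n_features = 2L, seed = 1L)
  # first 10 codons are the worked example; the rest map the second
  # expression starting at codon 11
  codons <- c(9, 8, 6, 4, 16, 10, 17, 23, 8, 14,
              2, 0, 1, rep(50, 17))
  fs <- build_feature_set(codons, cfg, g)
  expect_true(fs$valid)
  expect_length(fs$expressions, 2L)
  expect_equal(expr_to_string(fs$expressions[[1]]), "(x2+cos(x3))")
  expect_equal(expr_to_string(fs$expressions[[2]]), "x2")
  # recursive-only chromosome exhausts the wrap budget: invalid set
  bad <- build_feature_set(rep(0L, 20), cfg, g)
  expect_false(bad$valid)
})

test_that("RBF network interpolates and matches the least-squares oracle", {
  # constant target with a single node
  X <- matrix(rnorm(20), 10, 2)
  m <- train_rbf(X, rep(3, 10), k = 1L, seed = 1L)
  expect_equal(predict(m, X), rep(3, 10), tolerance = 1e-6)
  # XOR layout with one center per point interpolates
  Xx <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  tx <- c(0, 1, 1, 0)
  mx <- train_rbf(Xx, tx, k = 4L, seed = 2L)
  expect_lt(sum((predict(mx, Xx) - tx)^2), 1e-6)
  # output weights equal the normal-equations solution for the fitted
  # design matrix on a fixed 5-point, k = 2 instance
  set.seed(5)
  X5 <- matrix(rnorm(10), 5, 2)
  t5 <- c(0, 1, 0, 1, 1)
  m5 <- train_rbf(X5, t5, k = 2L, seed = 3L)
  Phi <- gefc:::rbf_design(m5, X5)
  w_oracle <- solve(t(Phi) %*% Phi + diag(1e-8, ncol(Phi)),
                    t(Phi) %*% t5)
  expect_equal(m5$weights, as.numeric(w_oracle), tolerance = 1e-6)
  # more nodes than patterns: reduced to the pattern count
  m_small <- train_rbf(X5, t5, k = 10L, seed = 4L)
  expect_lte(nrow(m_small$centers), 5L)
})

test_that("fitness penalizes invalid chromosomes and matches an SSE oracle", {
  tr <- make_toy_train()
  g <- default_feature_grammar(ncol(tr$X))
  cfg <- fc_config(n_features = 2L, seed = 6L)
  expect_equal(fc_fitness(rep(0L, 20), tr$X, tr$t, cfg, g),
               cfg$penalty_fitness)
  set.seed(60)
  repeat {
    codons <- sample(0:255, 100, replace = TRUE)
    fs <- build_feature_set(codons, cfg, g)
    if (fs$valid) break
  }
  f <- fc_fitness(codons, tr$X, tr$t, cfg, g)
  expect_gte(f, 0)
  if (f < cfg$penalty_fitness) {
    # recompute sum((C(x_hat) - t)^2) through the scalar evaluator and
    # the model's prediction path
    Z <- t(vapply(seq_len(nrow(tr$X)), function(r) {
      vapply(fs$expressions, function(e)
        evaluate_expression(e, tr$X[r, ])$value, numeric(1))
    }, numeric(cfg$n_features)))
    model <- train_rbf(Z, tr$t, k = cfg$rbf_nodes,
                       seed = gefc:::derive_seed(cfg$seed, "rbf"))
    expect_equal(f, sum((predict(model, Z) - tr$t)^2), tolerance = 1e-9)
  }
})

test_that("evolution is elitist, deterministic and size-preserving", {
  tr <- make_toy_train()
  cfg <- fc_config(generations = 10L, population = 20L, n_features = 2L,
                   seed = 3L)
  fs1 <- evolve_features(tr$X, tr$t, cfg)
  expect_length(fs1$expressions, 2L)
  expect_length(fs1$fitness_trace, 10L)
  expect_true(all(diff(fs1$fitness_trace) <= 0))
  expect_equal(fs1$best_fitness, min(fs1$fitness_trace))
  fs2 <- evolve_features(tr$X, tr$t, cfg)
  expect_identical(fs1$strings, fs2$strings)
  expect_identical(fs1$fitness_trace, fs2$fitness_trace)
})

test_that("evolved features beat identity features on a planted problem", {
  set.seed(14)
  M <- 80L
  X <- matrix(runif(M * 2, -1, 1), M, 2)
  t <- as.integer(X[, 1] * X[, 2] > 0)
  t <- ifelse(runif(M) < 0.05, 1L - t, t)  # 5% label noise
  cfg <- fc_config(generations = 20L, population = 50L, n_features = 2L,
                   seed = 9L)
  fs <- evolve_features(X, t, cfg)
  sse_identity <- {
    m <- train_rbf(X, t, k = cfg$rbf_nodes, seed = 1L)
    sum((predict(m, X) - t)^2)
  }
  expect_lt(fs$best_fitness, sse_identity)
})

test_that("dataset transformation preserves rows and matches re-evaluation", {
  tr <- make_toy_train(M = 30L)
  fm <- feature_matrix(tr$X, tr$t)
  cfg <- fc_config(generations = 5L, population = 20L, n_features = 3L,
                   seed = 12L)
  fs <- evolve_features(tr$X, tr$t, cfg)
  out <- transform_dataset(fm, fs)
  expect_equal(nrow(out$features), 30L)
  expect_equal(colnames(out$features), c("gf_1", "gf_2", "gf_3"))
  expect_identical(out$labels, fm$labels)
  for (r in c(1L, 15L, 30L)) {
    for (j in 1:3) {
      sc <- evaluate_expression(fs$expressions[[j]], tr$X[r, ])
      if (sc$finite) {
        expect_equal(as.numeric(out$features[r, j]), sc$value,
                     tolerance = 1e-12)
      }
    }
  }
  small <- feature_matrix(tr$X[, 1:2], tr$t)
  expect_error(transform_dataset(small, fs), "dimension")
})
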