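test_that("t-test score follows -log10(p + eps)", {
  cfg <- scoring_config()
  # perfect separation with constant paired difference drives p to 0,
  # and the epsilon guard caps the score at exactly 10
  pairing <- list(off = sprintf("P%d", 1:6), on = sprintf("P%d", 1:6))
  s <- ttest_score(c(1, 2, 3, 4, 5, 6) + 10, c(1, 2, 3, 4, 5, 6),
                   pairing = pairing, cfg = cfg)
  expect_equal(s, 10)
  # identical paired samples: p = 1, score ~ 0
  s0 <- ttest_score(c(1, 2, 3, 4, 5, 6), c(1, 2, 3, 4, 5, 6),
                    pairing = pairing, cfg = cfg)
  expect_lt(abs(s0), 1e-9)
  expect_error(
    ttest_score(1:3, 1:3, pairing = list(off = c("A", "B", "C"),
                                         on = c("A", "B", "D"))),
    "matching patient")
})

test_that("unpaired score matches a hand-computed Welch t-test", {
  set.seed(123)
  a <- rnorm(20, 0, 1)
  b <- rnorm(20, 1, 1.5)
  # Welch statistic and Satterthwaite df computed from first principles
  se2 <- var(a) / 20 + var(b) / 20
  tstat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((var(a) / 20)^2 / 19 + (var(b) / 20)^2 / 19)
  p <- 2 * pt(-abs(tstat), df)
  expect_equal(ttest_score(a, b), -log10(p + 1e-10), tolerance = 1e-9)
})

test_that("random-forest importance separates signal from noise", {
  set.seed(31)
  labels <- rep(c(0L, 1L), each = 20L)
  X <- cbind(signal = labels + rnorm(40, 0, 0.05), noise = rnorm(40))
  fm <- feature_matrix(X, labels)
  imp <- rf_gini_importance(fm, scoring_config(seed = 4))
  expect_gt(imp["signal"], imp["noise"])
  expect_true(all(imp >= 0))
  # determinism given the seed
  imp2 <- rf_gini_importance(fm, scoring_config(seed = 4))
  expect_identical(imp, imp2)
})

test_that("single-stump importance equals the hand-computed Gini decrease", {
  fm <- feature_matrix(matrix(c(1, 2, 3, 4), ncol = 1,
                              dimnames = list(NULL, "f")),
                       c(0L, 0L, 1L, 1L))
  imp <- rf_gini_importance(fm, scoring_config(n_trees = 1L, seed = 1L),
                            replace = FALSE, sampsize = 4L, mtry = 1L)
  # node-size-weighted decrease at the root: 4 * gini(2/4) - 2*0 - 2*0,
  # with gini(p) = sum_c p_c (1 - p_c) = 0.5 at the even split
  gini_root <- 2 * 0.5 * 0.5
  expect_equal(unname(imp["f"]), 4 * gini_root - 0 - 0)
})

test_that("PCA loading score respects symmetry and the 2x2 closed form", {
  set.seed(17)
  base <- rnorm(50)
  X <- cbind(a = base, b = base, c = rnorm(50))
  fm <- feature_matrix(X, rep(c(0L, 1L), 25))
  sc <- pca_loading_score(fm)
  expect_equal(sc[["a"]], sc[["b"]], tolerance = 1e-9)
  # analytic eigendecomposition of [[1, r], [r, 1]]: eigenvalues 1 +- r,
  # eigenvectors (1, 1)/sqrt(2) and (1, -1)/sqrt(2), so each column's
  # sum of absolute correlation loadings is (sqrt(1+r) + sqrt(1-r))/sqrt(2)
  n <- 2000
  set.seed(77)
  u <- rnorm(n); v <- rnorm(n)
  rho <- 0.6
  x1 <- u
  x2 <- rho * u + sqrt(1 - rho^2) * v
  fm2 <- feature_matrix(cbind(x1 = x1, x2 = x2), rep(c(0L, 1L), n / 2))
  r_emp <- cor(x1, x2)
  expected <- (sqrt(1 + r_emp) + sqrt(1 - r_emp)) / sqrt(2)
  sc2 <- pca_loading_score(fm2)
  expect_equal(unname(sc2), rep(expected, 2), tolerance = 1e-9)
  # zero-variance column scores 0
  fm3 <- feature_matrix(cbind(x = rnorm(10), z = rep(1, 10)),
                        rep(c(0L, 1L), 5))
  expect_equal(pca_loading_score(fm3)[["z"]], 0)
})

test_that("composite scores apply the 0.4/0.3/0.3 weighting", {
  raw <- data.frame(feature_name = c("a", "b"),
                    score_ttest = c(1, 0), score_rf = c(0, 1),
                    score_pca = c(0, 1))
  out <- composite_scores(raw)
  expect_equal(out$composite[out$feature_name == "a"], 0.4)
  expect_equal(out$composite[out$feature_name == "b"], 0.6)
  raw2 <- data.frame(feature_name = c("a", "b"),
                     score_ttest = c(1, 0), score_rf = c(1, 0),
                     score_pca = c(1, 0))
  out2 <- composite_scores(raw2)
  expect_equal(out2$composite[out2$feature_name == "a"], 1.0)
  expect_equal(sort(out2$rank), 1:2)
})

test_that("composite score is invariant to affine rescaling of raw scores", {
  set.seed(9)
  raw <- data.frame(feature_name = letters[1:8],
                    score_ttest = runif(8), score_rf = runif(8),
                    score_pca = runif(8))
  out1 <- composite_scores(raw)
  raw2 <- raw
  raw2$score_rf <- 100 * raw2$score_rf - 3  # min-max absorbs affine maps
  out2 <- composite_scores(raw2)
  expect_equal(out1$composite, out2$composite, tolerance = 1e-12)
  expect_equal(out1$rank, out2$rank)
})

test_that("constant raw vectors normalize to zero instead of NaN", {
  raw <- data.frame(feature_name = c("a", "b"),
                    score_ttest = c(0.5, 0.5), score_rf = c(1, 0),
                    score_pca = c(0, 0))
  out <- composite_scores(raw)
  expect_true(all(is.finite(out$composite)))
  expect_equal(out$norm_ttest, c(0, 0))
})

test_that("top-80% retention keeps floor(f * n) clamped to at least 1", {
  mk <- function(n) data.frame(feature_name = sprintf("f%02d", 1:n),
                               composite = seq(1, 0, length.out = n))
  expect_length(select_top_features(mk(20)), 16L)
  expect_length(select_top_features(mk(5)), 4L)
  expect_length(select_top_features(mk(1)), 1L)
  kept <- select_top_features(mk(10))
  expect_equal(kept[1], "f01")
})

test_that("score_features is deterministic and ranks the planted feature first", {
  fm <- make_toy_fm(n = 60, p = 5, shift = 3)
  sc1 <- score_features(fm, scoring_config(seed = 2, n_trees = 100L))
  sc2 <- score_features(fm, scoring_config(seed = 2, n_trees = 100L))
  expect_identical(sc1, sc2)
  expect_equal(sc1$feature_name[1], "f1")
  expect_equal(sort(sc1$rank), seq_len(nrow(sc1)))
})
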