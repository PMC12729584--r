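test_that("confusion-matrix metrics match direct arithmetic", {
  m <- compute_metrics(tp = 10, fp = 0, fn = 0, tn = 10)
  expect_equal(unname(m), c(0, 1, 1))
  m2 <- compute_metrics(tp = 8, fp = 2, fn = 2, tn = 8)
  expect_equal(unname(m2), c(20, 0.8, 0.8))
  # everything predicted positive on balanced data: 50% error
  m3 <- compute_metrics(tp = 10, fp = 10, fn = 0, tn = 0)
  expect_equal(unname(m3["error"]), 50)
  expect_error(compute_metrics(0, 0, 0, 0), "empty")
})

test_that("metric identities hold across random confusion matrices", {
  set.seed(88)
  for (i in 1:1000) {
    cm <- sample(0:30, 4, replace = TRUE)
    if (sum(cm) == 0) next
    m <- compute_metrics(cm[1], cm[2], cm[3], cm[4])
    tot <- sum(cm)
    expect_equal(unname(m["error"]), 100 * (cm[2] + cm[3]) / tot)
    pp <- if (cm[1] + cm[2] > 0) cm[1] / (cm[1] + cm[2]) else 0
    pn <- if (cm[4] + cm[3] > 0) cm[4] / (cm[4] + cm[3]) else 0
    expect_equal(unname(m["precision"]), (pp + pn) / 2)
    expect_true(m["error"] >= 0 && m["error"] <= 100)
    expect_true(m["precision"] >= 0 && m["precision"] <= 1)
  }
})

test_that("ROC analysis matches the concordant-pair oracle", {
  labels <- c(rep(1L, 5), rep(0L, 5))
  perfect <- c(6:10, 1:5) / 10
  expect_equal(roc_pr_points(perfect, labels)$auroc, 1)
  expect_equal(roc_pr_points(-perfect, labels)$auroc, 0)
  set.seed(71)
  for (i in 1:5) {
    scores <- runif(20)
    lab <- sample(c(rep(1L, 10), rep(0L, 10)))
    out <- roc_pr_points(scores, lab)
    expect_equal(out$auroc, oracle_auroc(scores, lab), tolerance = 1e-9)
    expect_equal(out$roc$fpr[1], 0)
    expect_equal(out$roc$tpr[nrow(out$roc)], 1)
  }
  expect_error(roc_pr_points(runif(5), rep(1L, 5)), "both classes")
  # independent library cross-check on one instance
  set.seed(6)
  sc <- rnorm(40)
  lb <- rep(c(0L, 1L), 20)
  auc_ref <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                            direction = "<")))
  expect_equal(roc_pr_points(sc, lb)$auroc, auc_ref, tolerance = 1e-9)
})

test_that("stratified folds are balanced and cover every row", {
  set.seed(12)
  labels <- sample(c(rep(0L, 33), rep(1L, 27)))
  folds <- gefc:::stratified_folds(labels, 10L, seed = 4L)
  expect_length(folds, 60L)
  sizes <- table(folds)
  expect_lte(max(sizes) - min(sizes), 1L)
  # per-class balance differs by at most one window
  for (cl in 0:1) {
    cs <- table(factor(folds[labels == cl], levels = 1:10))
    expect_lte(max(cs) - min(cs), 1L)
  }
  # grouped mode keeps each patient's windows in one fold
  groups <- rep(sprintf("P%d", 1:10), each = 6)
  gf <- gefc:::stratified_folds(labels, 5L, seed = 4L, groups = groups)
  for (g in unique(groups)) {
    expect_length(unique(gf[groups == g]), 1L)
  }
})

test_that("cross-validation scores a perfect oracle at zero error", {
  fm <- make_toy_fm(n = 60, p = 3, shift = 10)  # f1 separates perfectly
  oracle_method <- list(
    name = "oracle",
    fit = function(X, y, seed, cfg) mean(range(X[, 1])),
    predict = function(model, X) as.numeric(X[, 1] > model))
  rep <- crossval_evaluate(fm, oracle_method,
                           eval_config(folds = 5L, repeats = 2L, seed = 8L))
  expect_equal(rep$error, 0)
  expect_equal(rep$precision, 1)
  expect_equal(rep$recall, 1)
  expect_true(all(rep$per_fold$error >= 0))
  expect_true(rep$error >= min(rep$per_fold$error) &&
              rep$error <= max(rep$per_fold$error))
})

test_that("label-permuted data scores near chance level", {
  set.seed(202)
  n <- 100L
  X <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  fm <- feature_matrix(X, sample(rep(c(0L, 1L), n / 2)))
  rep <- crossval_evaluate(fm, method_rbf(),
                           eval_config(folds = 10L, repeats = 5L, seed = 31L))
  expect_gt(rep$error, 35)
  expect_lt(rep$error, 65)
})

test_that("baseline models train and behave as specified", {
  fm <- make_toy_fm(n = 60, p = 4, shift = 4)
  cfg <- eval_config(seed = 77L)
  # RBF on well-separated blobs: low training error
  rbf <- train_baseline(fm, "rbf", cfg)
  pred <- as.integer(predict(rbf, fm$features) >= 0.5)
  expect_lt(mean(pred != fm$labels), 0.05)
  # PCA baseline projects to exactly 2 components
  pca <- train_baseline(fm, "pca_mlp", cfg)
  expect_equal(pca$ncomp, 2L)
  proj <- predict(pca$pc, fm$features[, pca$keep])[, seq_len(pca$ncomp)]
  expect_equal(ncol(proj), 2L)
  # GA-trained MLP has a non-increasing fitness trace
  gen <- train_baseline(fm, "gen_mlp", cfg)
  expect_true(all(diff(gen$fitness_trace) <= 0))
  expect_error(train_baseline(fm, "nope", cfg))
})

test_that("feature construction in CV fits on training folds only", {
  fm <- make_toy_fm(n = 50, p = 3, shift = 3)
  fcc <- fc_config(generations = 3L, population = 12L, n_features = 2L,
                   seed = 5L)
  spec <- method_fc(fcc)
  ec <- eval_config(folds = 5L, repeats = 1L, seed = 19L)
  rep <- crossval_evaluate(fm, spec, ec)
  expect_true(is.finite(rep$error))
  expect_equal(nrow(rep$per_fold), 5L)
})
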