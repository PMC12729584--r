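# Shared fixtures, built once per test run. The default exercise-0
# cohort (the package's default simulation settings, seed 1) backs the
# synthetic-data and end-to-end checks.

.fixtures <- new.env(parent = emptyenv())

default_ex0_fixture <- function() {
  if (is.null(.fixtures$fm)) {
    cfg <- sim_config(seed = 1)
    cohort <- generate_cohort(cfg, exercises = 0)
    fm <- extract_feature_matrix(cohort_sessions(cohort, 0))
    .fixtures$cohort <- cohort
    .fixtures$fm <- fm
    .fixtures$scores <- score_features(fm)
  }
  list(cohort = .fixtures$cohort, fm = .fixtures$fm,
       scores = .fixtures$scores)
}

# small labelled feature matrix with one informative column
make_toy_fm <- function(n = 40L, p = 4L, seed = 99L, shift = 2) {
  set.seed(seed)
  labels <- rep(c(0L, 1L), each = n / 2L)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  X[, 1] <- X[, 1] + shift * labels
  feature_matrix(X, labels)
}

# tiny regression set for GA runs: target depends nonlinearly on x1, x2
make_toy_train <- function(M = 60L, d = 5L, seed = 7L) {
  set.seed(seed)
  X <- matrix(runif(M * d, -1, 1), M, d)
  t <- as.integer(X[, 1] * X[, 2] > 0)
  list(X = X, t = t)
}
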