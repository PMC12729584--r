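test_that("magnitude signal is the per-sample Euclidean norm", {
  s <- triaxial_series(rep(3, 5), rep(4, 5), rep(0, 5))
  expect_equal(magnitude_signal(s), rep(5, 5))
  z <- triaxial_series(rep(0, 4), rep(0, 4), rep(0, 4))
  expect_equal(magnitude_signal(z), rep(0, 4))
  set.seed(42)
  x <- rnorm(10); y <- rnorm(10); zc <- rnorm(10)
  expect_equal(magnitude_signal(triaxial_series(x, y, zc)),
               oracle_magnitude(x, y, zc), tolerance = 1e-12)
  expect_error(triaxial_series(numeric(0), numeric(0), numeric(0)),
               "non-empty")
})

test_that("sliding window count follows floor((N - L) / step) + 1", {
  expect_length(sliding_windows(rnorm(100), window_spec(100, 50)), 1L)
  expect_length(sliding_windows(rnorm(250), window_spec(100, 50)), 4L)
  expect_length(sliding_windows(rnorm(99), window_spec(100, 50)), 0L)
  set.seed(3)
  for (i in 1:50) {
    n <- sample(1:300, 1)
    len <- sample(1:120, 1)
    step <- sample(1:len, 1)
    w <- sliding_windows(seq_len(n), window_spec(len, step))
    starts <- oracle_window_starts(n, len, step)
    expect_length(w, length(starts))
    if (length(w)) {
      expect_equal(vapply(w, `[`, 0, 1), as.numeric(starts))
      expect_true(all(lengths(w) == len))
    }
  }
})

test_that("statistical features handle constants, symmetry and match the mean", {
  const <- statistical_features(rep(2.5, 30))
  expect_equal(unname(const[c("std", "var", "range", "iqr",
                              "quartile_deviation", "skewness",
                              "kurtosis")]),
               rep(0, 7))
  sym <- statistical_features(c(-3, -2, -1, 0, 1, 2, 3))
  expect_equal(unname(sym["skewness"]), 0)
  w <- 1:100
  expect_equal(unname(statistical_features(w)["mean"]), sum(w) / 100)
  expect_error(statistical_features(1), "length")
})

test_that("features shift as documented under v -> v + c", {
  set.seed(11)
  w <- rnorm(60)
  a <- c(statistical_features(w), nonlinear_features(w))
  b <- c(statistical_features(w + 5), nonlinear_features(w + 5))
  expect_equal(b[["mean"]], a[["mean"]] + 5)
  for (f in c("std", "iqr", "mad", "rmssd")) {
    expect_equal(b[[f]], a[[f]], tolerance = 1e-12, label = f)
  }
})

test_that("energy features match closed forms", {
  z <- energy_features(rep(0, 10))
  expect_equal(unname(z[c("sma", "rms", "total_energy")]), c(0, 0, 0))
  cst <- energy_features(rep(2, 100))
  expect_equal(unname(cst["rms"]), 2)
  expect_equal(unname(cst["total_energy"]), 400)
  tt <- (0:199) / 100
  sine <- energy_features(3 * sin(2 * pi * 5 * tt))
  expect_equal(unname(sine["rms"]), 3 / sqrt(2), tolerance = 1e-6)
})

test_that("spectral features identify tones, flat spectra and flux", {
  tt <- (0:99) / 100
  tone <- spectral_features(sin(2 * pi * 5 * tt), fs = 100)
  expect_equal(unname(tone["dominant_frequency"]), 5)
  expect_lt(unname(tone["spectral_spread"]), 0.05)
  # an impulse has equal power in every bin
  imp <- spectral_features(c(1, rep(0, 99)), fs = 100)
  expect_equal(unname(imp["spectral_flatness"]), 1, tolerance = 1e-9)
  expect_equal(unname(imp["spectral_entropy"]), 1, tolerance = 1e-9)
  set.seed(5)
  w <- rnorm(100)
  f1 <- spectral_features(w, 100)
  f2 <- spectral_features(w, 100, prev_spectrum = attr(f1, "spectrum"))
  expect_equal(unname(f2["spectral_flux"]), 0)
  expect_equal(unname(f1["spectral_flux"]), 0)
  expect_error(spectral_features(c(1, 2, 3), 100), "length")
})

test_that("nonlinear features match sentinels and simple closed forms", {
  cst <- nonlinear_features(rep(1, 30))
  expect_equal(unname(cst[c("mad", "rmssd")]), c(0, 0))
  alt <- nonlinear_features(rep(c(1, -1), 15))
  expect_equal(unname(alt["rmssd"]), 2)
  # near-straight line has fractal dimension about 1
  line <- seq(0, 1, length.out = 50)
  expect_equal(higuchi_fd(line), 1, tolerance = 0.05)
  expect_error(nonlinear_features(rnorm(10)), "length")
})

test_that("entropy and complexity estimators agree with brute-force oracles", {
  set.seed(21)
  for (i in 1:5) {
    x <- rnorm(30 + 4 * i)
    expect_equal(sample_entropy(x, m = 2L, r = 0.2 * sd(x)),
                 oracle_sampen(x, m = 2L, r = 0.2 * sd(x)),
                 tolerance = 1e-9)
    expect_equal(higuchi_fd(x, k_max = 10L), oracle_higuchi(x, 10L),
                 tolerance = 1e-9)
  }
})

test_that("all features are finite on arbitrary finite windows", {
  set.seed(8)
  cases <- list(rnorm(100), rep(0, 100), rexp(100),
                c(rep(1, 50), rep(-1, 50)), cumsum(rnorm(100)))
  for (w in cases) {
    f <- c(statistical_features(w), energy_features(w),
           spectral_features(w, 100), nonlinear_features(w))
    expect_true(all(is.finite(f)))
  }
})

test_that("feature matrix extraction yields 87 named columns and window rows", {
  set.seed(13)
  mk <- function(n) triaxial_series(rnorm(n), rnorm(n), rnorm(n))
  sess <- recording_session("P01", 0, "OFF",
                            list(acce = mk(250), gyro = mk(250),
                                 magn = mk(250)))
  fm <- extract_feature_matrix(list(sess))
  expect_equal(dim(fm), c(4L, 87L))
  expect_equal(ncol(fm$features), 3L * length(feature_bank()))
  expect_true(all(fm$labels == 0L))
  expect_equal(colnames(fm$features)[1], "acce_mean")
  expect_true("gyro_sample_entropy" %in% colnames(fm$features))
  sess_on <- recording_session("P01", 1, "ON",
                               list(acce = mk(250), gyro = mk(250),
                                    magn = mk(250)))
  expect_error(extract_feature_matrix(list(sess, sess_on)), "exercise")
})
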