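#' The fixed 29-name feature bank
#'
#' Names, in canonical order, of the descriptors computed on every
#' window of a sensor magnitude signal: 12 statistical, 4 energy,
#' 8 spectral and 5 dynamic/nonlinear features.
#'
#' @return Character vector of length 29.
#' @export
feature_bank <- function() {
  c(
    # statistical
    "mean", "median", "std", "var", "min", "max", "range",
    "skewness", "kurtosis", "iqr", "quartile_deviation", "cv",
    # energy
    "sma", "rms", "total_energy", "log_energy",
    # spectral
    "dominant_frequency", "spectral_flatness", "spectral_flux",
    "spectral_variability", "spectral_entropy", "spectral_centroid",
    "spectral_spread", "spectral_rolloff",
    # dynamic / nonlinear
    "mad", "rmssd", "higuchi_fractal_dimension", "lyapunov_exponent",
    "sample_entropy"
  )
}

sensor_names <- function() c("acce", "gyro", "magn")

#' Construct a tri-axial sensor series
#'
#' @param x,y,z Equal-length numeric vectors (sensor units).
#' @param fs Sampling rate in Hz (default 100).
#' @return An object of class `triaxial_series`.
#' @export
triaxial_series <- function(x, y, z, fs = 100) {
  stopifnot(is.numeric(x), is.numeric(y), is.numeric(z))
  if (length(x) == 0L) stop("series must be non-empty")
  if (length(x) != length(y) || length(x) != length(z)) {
    stop("x, y, z must have equal length")
  }
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive")
  structure(list(x = as.double(x), y = as.double(y), z = as.double(z),
                 fs = fs),
            class = "triaxial_series")
}

#' Construct a recording session
#'
#' One patient x exercise x medication-state recording holding the
#' accelerometer, gyroscope and magnetometer streams.
#'
#' @param patient_id Character scalar.
#' @param exercise Integer in 0..3 (rest tremor, postural, finger
#'   tapping, hand open-close).
#' @param state `"OFF"` or `"ON"`.
#' @param sensors Named list with elements `acce`, `gyro`, `magn`, each
#'   a [triaxial_series()].
#' @return An object of class `recording_session`.
#' @export
recording_session <- function(patient_id, exercise, state, sensors) {
  stopifnot(is.character(patient_id), length(patient_id) == 1L)
  exercise <- as.integer(exercise)
  if (!exercise %in% 0:3) stop("exercise must be in 0..3")
  state <- match.arg(state, c("OFF", "ON"))
  if (!all(sensor_names() %in% names(sensors))) {
    stop("sensors must contain acce, gyro and magn")
  }
  fss <- vapply(sensors[sensor_names()], function(s) s$fs, numeric(1))
  if (length(unique(fss)) != 1L) stop("all sensors must share fs")
  structure(list(patient_id = patient_id, exercise = exercise,
                 state = state, sensors = sensors[sensor_names()]),
            class = "recording_session")
}

#' Sliding-window specification
#'
#' @param length_samples Window length (default 100 samples = 1 s at
#'   100 Hz).
#' @param step_samples Hop between window starts (default 50, i.e. 50%
#'   overlap).
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(length_samples = 100L, step_samples = 50L) {
  length_samples <- as.integer(length_samples)
  step_samples <- as.integer(step_samples)
  if (length_samples < 1L) stop("length_samples must be positive")
  if (step_samples < 1L || step_samples > length_samples) {
    stop("step_samples must satisfy 0 < step <= length")
  }
  structure(list(length_samples = length_samples,
                 step_samples = step_samples),
            class = "window_spec")
}

#' Magnitude of a tri-axial signal
#'
#' Per-sample Euclidean norm `sqrt(x^2 + y^2 + z^2)`; all downstream
#' features are computed on this combined magnitude signal.
#'
#' @param series A [triaxial_series()].
#' @return Numeric vector of the same length as the input axes.
#' @export
magnitude_signal <- function(series) {
  stopifnot(inherits(series, "triaxial_series"))
  sqrt(series$x^2 + series$y^2 + series$z^2)
}

#' Cut a signal into sliding windows
#'
#' Windows start at 0, step, 2*step, ... (0-based); trailing partial
#' windows are discarded, so a signal shorter than one window yields an
#' empty list.
#'
#' @param signal Numeric vector.
#' @param spec A [window_spec()].
#' @return List of numeric vectors, each of length
#'   `spec$length_samples`.
#' @export
sliding_windows <- function(signal, spec = window_spec()) {
  stopifnot(inherits(spec, "window_spec"))
  n <- length(signal)
  L <- spec$length_samples
  step <- spec$step_samples
  if (n < L) return(list())
  starts <- seq.int(1L, n - L + 1L, by = step)
  lapply(starts, function(s) signal[s:(s + L - 1L)])
}

#' Statistical window features
#'
#' Central tendency, dispersion and distribution-shape descriptors.
#' Skewness and kurtosis use population (biased) moments, kurtosis is
#' reported as excess kurtosis, and both fall back to 0 on constant
#' windows. The coefficient of variation is `sd / |mean|` with sentinel
#' 0 when `|mean| < 1e-12`. Quartile deviation is `(Q3 - Q1) / 2`.
#'
#' @param window Numeric vector of length >= 2.
#' @return Named numeric vector of 12 values.
#' @export
statistical_features <- function(window) {
  if (length(window) < 2L) stop("window must have length >= 2")
  m <- mean(window)
  s <- stats::sd(window)
  q <- stats::quantile(window, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  m2 <- mean((window - m)^2)
  if (m2 > 0) {
    skew <- mean((window - m)^3) / m2^1.5
    kurt <- mean((window - m)^4) / m2^2 - 3
  } else {
    skew <- 0
    kurt <- 0
  }
  cv <- if (abs(m) < 1e-12) 0 else s / abs(m)
  c(mean = m, median = stats::median(window), std = s, var = s^2,
    min = min(window), max = max(window), range = max(window) - min(window),
    skewness = skew, kurtosis = kurt, iqr = iqr,
    quartile_deviation = iqr / 2, cv = cv)
}

#' Energy window features
#'
#' Signal magnitude area (mean absolute value), root mean square, total
#' energy (sum of squares) and logarithmic energy
#' `sum(log(v^2 + 1e-12))`, where the small constant guards zeros.
#'
#' @param window Numeric vector.
#' @return Named numeric vector of 4 values.
#' @export
energy_features <- function(window) {
  stopifnot(length(window) >= 1L)
  c(sma = mean(abs(window)),
    rms = sqrt(mean(window^2)),
    total_energy = sum(window^2),
    log_energy = sum(log(window^2 + 1e-12)))
}

# One-sided power spectrum of the mean-removed window (rectangular
# taper), excluding the DC bin. Returns power per bin and bin
# frequencies in Hz.
power_spectrum <- function(window, fs) {
  n <- length(window)
  v <- window - mean(window)
  sp <- stats::fft(v)
  nb <- n %/% 2L
  p <- Mod(sp[2:(nb + 1L)])^2 / n
  freqs <- (1:nb) * fs / n
  list(power = p, freqs = freqs)
}

#' Spectral window features
#'
#' Eight descriptors of the one-sided power spectrum of the
#' mean-removed window (rectangular taper, DC bin excluded): dominant
#' frequency, flatness (geometric/arithmetic mean ratio), flux
#' (Euclidean distance to the previous window's spectrum, 0 for the
#' first window), variability (standard deviation of the normalised
#' spectrum), entropy (normalised to \[0, 1\]), centroid, spread and
#' 85% roll-off. A window with (numerically) zero spectral power
#' returns the sentinel 0 for every descriptor except flux.
#'
#' @param window Numeric vector of length >= 4.
#' @param fs Sampling rate in Hz.
#' @param prev_spectrum Optional power spectrum of the preceding window
#'   (as returned in the `"spectrum"` attribute) used for spectral flux.
#' @return Named numeric vector of 8 values with the raw power spectrum
#'   attached as attribute `"spectrum"`.
#' @export
spectral_features <- function(window, fs = 100, prev_spectrum = NULL) {
  if (length(window) < 4L) stop("window must have length >= 4")
  ps <- power_spectrum(window, fs)
  p <- ps$power
  freqs <- ps$freqs
  total <- sum(p)
  flux <- if (is.null(prev_spectrum)) 0 else sqrt(sum((p - prev_spectrum)^2))
  if (total < 1e-300) {
    out <- c(dominant_frequency = 0, spectral_flatness = 0,
             spectral_flux = flux, spectral_variability = 0,
             spectral_entropy = 0, spectral_centroid = 0,
             spectral_spread = 0, spectral_rolloff = 0)
    attr(out, "spectrum") <- p
    return(out)
  }
  pn <- p / total
  dominant <- freqs[which.max(p)]
  flatness <- exp(mean(log(p + 1e-300))) / mean(p)
  entropy <- if (length(pn) > 1L) {
    -sum(ifelse(pn > 0, pn * log(pn), 0)) / log(length(pn))
  } else 0
  centroid <- sum(freqs * pn)
  spread <- sqrt(sum((freqs - centroid)^2 * pn))
  rolloff <- freqs[which(cumsum(pn) >= 0.85)[1]]
  out <- c(dominant_frequency = dominant, spectral_flatness = flatness,
           spectral_flux = flux, spectral_variability = stats::sd(pn),
           spectral_entropy = entropy, spectral_centroid = centroid,
           spectral_spread = spread, spectral_rolloff = rolloff)
  attr(out, "spectrum") <- p
  out
}

#' Dynamic and nonlinear window features
#'
#' Mean absolute deviation about the mean, RMSSD (root mean square of
#' successive differences), Higuchi fractal dimension (k_max = 10),
#' a Rosenstein-style largest Lyapunov exponent (embedding dimension 2,
#' delay 1, divergence fit over 10 steps, units 1/sample) and sample
#' entropy (m = 2, r = 0.2 sd, Chebyshev distance, self-matches
#' excluded). Degenerate windows (constant, or too short for neighbour
#' searches) return the documented sentinel 0 for the affected
#' descriptor.
#'
#' @param window Numeric vector of length >= 20.
#' @return Named numeric vector of 5 values.
#' @export
nonlinear_features <- function(window) {
  if (length(window) < 20L) stop("window must have length >= 20")
  d <- diff(window)
  c(mad = mean(abs(window - mean(window))),
    rmssd = sqrt(mean(d^2)),
    higuchi_fractal_dimension = higuchi_fd(window, k_max = 10L),
    lyapunov_exponent = lyapunov_rosenstein(window),
    sample_entropy = sample_entropy(window, m = 2L, r = 0.2 * stats::sd(window)))
}

#' Higuchi fractal dimension
#'
#' Curve-length estimate: for each scale `k` in 1..`k_max` the mean
#' normalised curve length `L(k)` over the `k` possible offsets is
#' computed, and the fractal dimension is the least-squares slope of
#' `log(L(k))` versus `log(1/k)`. A straight line has dimension ~1;
#' a constant window returns the sentinel 0.
#'
#' @param x Numeric vector.
#' @param k_max Largest scale (default 10).
#' @return Scalar fractal dimension estimate.
#' @export
higuchi_fd <- function(x, k_max = 10L) {
  n <- length(x)
  ks <- seq_len(min(k_max, n %/% 2L))
  if (length(ks) < 2L) return(0)
  lk <- vapply(ks, function(k) {
    lm_k <- vapply(seq_len(k), function(m) {
      idx <- seq.int(m, n, by = k)
      if (length(idx) < 2L) return(NA_real_)
      nm <- length(idx) - 1L
      # Higuchi's normalisation: (n - 1) / (nm * k) corrects for the
      # number of differences available at offset m and scale k.
      sum(abs(diff(x[idx]))) * (n - 1) / (nm * k) / k
    }, numeric(1))
    mean(lm_k, na.rm = TRUE)
  }, numeric(1))
  if (any(lk <= 0) || any(!is.finite(lk))) return(0)
  unname(stats::coef(stats::lm.fit(cbind(1, log(1 / ks)), log(lk)))[2])
}

#' Sample entropy
#'
#' Negative log conditional probability that windows similar for `m`
#' samples (Chebyshev distance <= `r`, self-matches excluded) remain
#' similar for `m + 1` samples. Returns the sentinel 0 when no template
#' matches exist at either length (the log would be undefined).
#'
#' @param x Numeric vector.
#' @param m Template length (default 2).
#' @param r Tolerance (default `0.2 * sd(x)`).
#' @return Scalar sample entropy.
#' @export
sample_entropy <- function(x, m = 2L, r = 0.2 * stats::sd(x)) {
  n <- length(x)
  if (n <= m + 1L || r <= 0) return(0)
  # templates start at 1..n-m at both lengths, so every length-m
  # template compared can be extended to length m + 1
  nb <- n - m
  D <- abs(outer(x, x, "-"))
  Dm <- D[seq_len(nb), seq_len(nb)]
  for (k in seq_len(m - 1L)) {
    Dm <- pmax(Dm, D[k + seq_len(nb), k + seq_len(nb)])
  }
  Dm1 <- pmax(Dm, D[m + seq_len(nb), m + seq_len(nb)])
  up <- upper.tri(Dm)
  B <- sum(Dm[up] <= r)
  A <- sum(Dm1[up] <= r)
  if (B == 0L || A == 0L) return(0)
  -log(A / B)
}

#' Largest Lyapunov exponent (Rosenstein method)
#'
#' Delay embedding with dimension 2 and delay 1; for each embedded
#' point the nearest neighbour outside a Theiler window of 1 is found,
#' the mean log divergence is tracked over the first 10 steps, and the
#' exponent is the least-squares slope of that curve (units 1/sample).
#' Windows too short or too regular for valid neighbour pairs return
#' the sentinel 0.
#'
#' @param x Numeric vector.
#' @param n_steps Number of divergence steps fitted (default 10).
#' @return Scalar exponent estimate.
#' @export
lyapunov_rosenstein <- function(x, n_steps = 10L) {
  n <- length(x) - 1L  # embedded points (x_i, x_{i+1})
  if (n < n_steps + 3L) return(0)
  emb <- cbind(x[1:n], x[2:(n + 1L)])
  # nearest neighbour per point, Theiler window 1
  D2 <- outer(emb[, 1], emb[, 1], "-")^2 + outer(emb[, 2], emb[, 2], "-")^2
  D2[abs(row(D2) - col(D2)) <= 1L] <- Inf
  nn <- max.col(-D2, ties.method = "first")
  mean_log_div <- rep(NA_real_, n_steps + 1L)
  for (t in 0:n_steps) {
    ok <- which(seq_len(n) + t <= n & nn + t <= n)
    if (length(ok) == 0L) next
    di <- sqrt((emb[ok + t, 1] - emb[nn[ok] + t, 1])^2 +
               (emb[ok + t, 2] - emb[nn[ok] + t, 2])^2)
    di <- di[di > 0]
    if (length(di) == 0L) next
    mean_log_div[t + 1L] <- mean(log(di))
  }
  ok <- which(!is.na(mean_log_div))
  if (length(ok) < 2L) return(0)
  tt <- (ok - 1L)
  unname(stats::coef(stats::lm.fit(cbind(1, tt), mean_log_div[ok]))[2])
}

# All 29 features for one window (magnitude domain).
window_features <- function(window, fs, prev_spectrum = NULL) {
  sf <- spectral_features(window, fs, prev_spectrum)
  out <- c(statistical_features(window), energy_features(window),
           sf[names(sf)], nonlinear_features(window))
  structure(out[feature_bank()], spectrum = attr(sf, "spectrum"))
}

#' Extract the windowed feature matrix from recording sessions
#'
#' Each session's three sensor streams are reduced to their magnitude
#' signal, cut into sliding windows, and summarised by the 29-feature
#' bank, giving 87 columns named `{sensor}_{feature}`. Rows are
#' labelled 0 (OFF) / 1 (ON) from the session state. Spectral flux
#' chains consecutive windows of the same sensor stream (first window
#' 0). All sessions must share one exercise; one matrix is produced per
#' exercise.
#'
#' @param sessions List of [recording_session()] objects.
#' @param spec A [window_spec()].
#' @return A `feature_matrix` object: list with `features` (numeric
#'   matrix), `labels` (integer 0/1), `meta` (data.frame with
#'   patient_id, window_index, state), and `exercise`.
#' @export
extract_feature_matrix <- function(sessions, spec = window_spec()) {
  stopifnot(length(sessions) >= 1L)
  exercises <- vapply(sessions, function(s) s$exercise, integer(1))
  if (length(unique(exercises)) != 1L) {
    stop("all sessions must share one exercise; got: ",
         paste(sort(unique(exercises)), collapse = ", "))
  }
  cols <- as.vector(t(outer(sensor_names(), feature_bank(), paste, sep = "_")))
  rows <- list()
  labels <- integer(0)
  meta <- list(patient_id = character(0), window_index = integer(0),
               state = character(0))
  for (sess in sessions) {
    per_sensor <- lapply(sensor_names(), function(sn) {
      ser <- sess$sensors[[sn]]
      mag <- magnitude_signal(ser)
      wins <- sliding_windows(mag, spec)
      prev <- NULL
      mat <- matrix(NA_real_, length(wins), length(feature_bank()))
      for (w in seq_along(wins)) {
        f <- window_features(wins[[w]], ser$fs, prev)
        prev <- attr(f, "spectrum")
        mat[w, ] <- as.numeric(f)
      }
      mat
    })
    nw <- nrow(per_sensor[[1]])
    if (nw == 0L) next
    block <- do.call(cbind, per_sensor)
    rows[[length(rows) + 1L]] <- block
    labels <- c(labels, rep(if (sess$state == "ON") 1L else 0L, nw))
    meta$patient_id <- c(meta$patient_id, rep(sess$patient_id, nw))
    meta$window_index <- c(meta$window_index, seq_len(nw) - 1L)
    meta$state <- c(meta$state, rep(sess$state, nw))
  }
  features <- do.call(rbind, rows)
  colnames(features) <- cols
  feature_matrix(features, labels, as.data.frame(meta),
                 exercise = sessions[[1]]$exercise)
}

#' Construct a feature matrix container
#'
#' @param features Numeric matrix with column names.
#' @param labels Integer vector of 0 (OFF) / 1 (ON), one per row.
#' @param meta Optional data.frame of row metadata (patient_id,
#'   window_index, ...).
#' @param exercise Optional exercise id.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(features, labels, meta = NULL, exercise = NA_integer_) {
  features <- as.matrix(features)
  if (is.null(colnames(features))) {
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  }
  labels <- as.integer(labels)
  if (nrow(features) != length(labels)) {
    stop("features and labels must have matching length")
  }
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  if (is.null(meta)) {
    meta <- data.frame(patient_id = rep(NA_character_, nrow(features)),
                       window_index = seq_len(nrow(features)) - 1L,
                       state = ifelse(labels == 1L, "ON", "OFF"))
  }
  structure(list(features = features, labels = labels, meta = meta,
                 exercise = exercise),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d windows x %d features (exercise %s)\n",
              nrow(x$features), ncol(x$features), x$exercise))
  cat(sprintf("  labels: %d OFF, %d ON\n",
              sum(x$labels == 0L), sum(x$labels == 1L)))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$features)
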