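#' Synthetic cohort configuration
#'
#' Parameters of the glove-IMU simulator. The defaults encode the
#' contrast the classifier is meant to detect: in the OFF state the
#' 4-6 Hz tremor is larger and less regular (more phase/amplitude
#' jitter) and repetitive tasks are slower; after medication (ON) the
#' tremor is attenuated and steadier and tapping speeds up.
#'
#' @param n_patients Number of simulated patients (default 14).
#' @param fs Sampling rate in Hz (default 100).
#' @param duration_s Recording length in seconds per exercise; a
#'   vector of four values for exercises 0-3 (default
#'   `c(10, 13, 16, 12)`, chosen so a cohort yields a few hundred
#'   windows per class per exercise) or a scalar recycled to all four.
#' @param tremor_band Tremor frequency range in Hz (default `c(4, 6)`);
#'   each patient draws one resting frequency from it.
#' @param tremor_amp_off,tremor_amp_on Tremor amplitude per state
#'   (defaults 1.0 and 0.4; OFF must exceed ON).
#' @param jitter_off,jitter_on Phase/amplitude noise scale per state
#'   (defaults 0.3 and 0.1).
#' @param tap_rate_off,tap_rate_on Repetition rate in Hz of the tapping
#'   and open-close tasks (defaults 1.5 and 2.5: bradykinetic OFF
#'   movement is slower).
#' @param noise_sd White sensor-noise standard deviation (default
#'   0.05).
#' @param seed Integer seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 14L, fs = 100, duration_s = c(10, 13, 16, 12),
                       tremor_band = c(4, 6), tremor_amp_off = 1.0,
                       tremor_amp_on = 0.4, jitter_off = 0.3,
                       jitter_on = 0.1, tap_rate_off = 1.5,
                       tap_rate_on = 2.5, noise_sd = 0.05, seed = 1L) {
  if (tremor_amp_on >= tremor_amp_off) {
    stop("tremor_amp_on must be smaller than tremor_amp_off")
  }
  stopifnot(n_patients >= 1L, fs > 0, all(duration_s > 0),
            length(tremor_band) == 2L, tremor_band[1] < tremor_band[2],
            noise_sd >= 0)
  if (length(duration_s) == 1L) duration_s <- rep(duration_s, 4L)
  stopifnot(length(duration_s) == 4L)
  structure(list(n_patients = as.integer(n_patients), fs = fs,
                 duration_s = duration_s, tremor_band = tremor_band,
                 tremor_amp_off = tremor_amp_off,
                 tremor_amp_on = tremor_amp_on,
                 jitter_off = jitter_off, jitter_on = jitter_on,
                 tap_rate_off = tap_rate_off, tap_rate_on = tap_rate_on,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw per-patient simulation parameters
#'
#' Each patient gets a personal resting tremor frequency (uniform on
#' the tremor band), a baseline amplitude scale (log-normal, roughly
#' 0.4x-2.5x) and a personal roughness multiplier applied to both
#' states. The wide amplitude spread means some patients' medicated
#' tremor exceeds other patients' unmedicated tremor, so absolute
#' amplitude features are patient-confounded and the within-patient
#' medication contrast has to be found in relative/regularity
#' structure — the situation a pooled-window classifier faces in a
#' real cohort.
#'
#' @param cfg A [sim_config()].
#' @return Data frame with one row per patient.
#' @export
draw_patient_params <- function(cfg) {
  with_local_seed(cfg$seed, {
    data.frame(
      patient_id = sprintf("P%02d", seq_len(cfg$n_patients)),
      tremor_freq = stats::runif(cfg$n_patients, cfg$tremor_band[1],
                                 cfg$tremor_band[2]),
      amp_scale = stats::rlnorm(cfg$n_patients, 0, 0.45),
      jitter_scale = stats::runif(cfg$n_patients, 0.6, 1.6),
      stringsAsFactors = FALSE)
  })
}

# random 3-D rotation matrix (axis-angle) coupling the axes of a
# session; the angle is bounded because a worn glove wobbles around a
# task-imposed posture rather than taking a uniformly random attitude
random_rotation <- function(max_angle = 0.6) {
  axis <- stats::rnorm(3)
  axis <- axis / sqrt(sum(axis^2))
  theta <- stats::runif(1, 0, max_angle)
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Simulate one recording session
#'
#' Builds tri-axial accelerometer, gyroscope and magnetometer streams
#' for one patient x exercise x state combination:
#' * a tremor sinusoid at the patient's personal 4-6 Hz frequency with
#'   state-dependent amplitude and phase/amplitude jitter,
#' * a task component — postural drift (exercise 1) or periodic
#'   Gaussian tap bursts at the state-dependent rate (exercises 2-3),
#' * gravity offset on the accelerometer, differentiated oscillation on
#'   the gyroscope, slow orientation drift with attenuated tremor on
#'   the magnetometer,
#' * white sensor noise, with all three axes coupled through one random
#'   per-session rotation.
#'
#' @param patient_params One row of [draw_patient_params()].
#' @param exercise Integer in 0..3.
#' @param state `"OFF"` or `"ON"`.
#' @param cfg A [sim_config()].
#' @param seed Integer seed; the same seed reproduces the session
#'   bit for bit.
#' @return A [recording_session()].
#' @export
simulate_session <- function(patient_params, exercise, state, cfg,
                             seed = cfg$seed) {
  exercise <- as.integer(exercise)
  if (!exercise %in% 0:3) stop("exercise must be in 0..3")
  state <- match.arg(state, c("OFF", "ON"))
  fs <- cfg$fs
  n <- as.integer(round(cfg$duration_s[exercise + 1L] * fs))
  tt <- (seq_len(n) - 1L) / fs
  amp <- (if (state == "OFF") cfg$tremor_amp_off else cfg$tremor_amp_on) *
    patient_params$amp_scale
  jitter <- (if (state == "OFF") cfg$jitter_off else cfg$jitter_on) *
    patient_params$jitter_scale
  tap_rate <- if (state == "OFF") cfg$tap_rate_off else cfg$tap_rate_on
  f0 <- patient_params$tremor_freq

  with_local_seed(seed, {
    # tremor with phase random walk and slow amplitude modulation
    phase <- 2 * pi * f0 * tt + cumsum(stats::rnorm(n, 0, jitter * 0.15))
    amp_mod <- 1 + jitter * sin(2 * pi * 0.3 * tt +
                                  stats::runif(1, 0, 2 * pi)) +
      jitter * 0.5 * cumsum(stats::rnorm(n, 0, 0.01))
    trem <- amp * amp_mod * sin(phase)
    trem_deriv <- amp * amp_mod * 2 * pi * f0 * cos(phase) / (2 * pi * 6)
    # movement roughness: high-frequency jerk irregularity accompanying
    # the tremor (first-difference noise, so the power sits near the
    # Nyquist band), scaled by the state's jitter level; this is what
    # the regularity descriptors (RMSSD, sample entropy, Lyapunov,
    # spectral shape) pick up
    w <- stats::rnorm(n)
    rough <- jitter * amp * (w - c(0, w[-n])) / sqrt(2)

    task <- numeric(n)
    task_deriv <- numeric(n)
    if (exercise == 1L) {
      task <- 0.5 * sin(2 * pi * 0.25 * tt + stats::runif(1, 0, 2 * pi))
      task_deriv <- 0.5 * 2 * pi * 0.25 *
        cos(2 * pi * 0.25 * tt) / (2 * pi * 6)
    } else if (exercise >= 2L) {
      scale <- if (exercise == 3L) 2.0 else 1.2
      centers <- seq(0.3, max(tt), by = 1 / tap_rate) +
        stats::rnorm(ceiling(max(tt) * tap_rate), 0, 0.02)
      for (tc in centers) {
        burst <- scale * exp(-((tt - tc)^2) / (2 * 0.05^2)) *
          sin(2 * pi * 8 * (tt - tc))
        task <- task + burst
      }
      task_deriv <- c(0, diff(task)) * fs / (2 * pi * 6)
    }

    R <- random_rotation()
    # tremor acceleration mostly normal to the resting palm (vertical)
    dir_a <- R %*% c(0.4, 0.3, 1)
    noise <- function(scale = 1) {
      matrix(stats::rnorm(3L * n, 0, cfg$noise_sd * scale), 3L, n)
    }

    sig_a <- trem + task + 0.3 * rough
    acce_m <- dir_a %*% t(cbind(sig_a)) + c(0.1, 0.2, 9.81) + noise()
    dir_g <- R %*% c(0.3, 1, 0.5)
    sig_g <- trem_deriv + task_deriv + 0.8 * rough
    gyro_m <- dir_g %*% t(cbind(sig_g)) + noise(0.5)
    drift <- 0.8 * sin(2 * pi * 0.05 * tt + stats::runif(1, 0, 2 * pi))
    dir_m <- R %*% c(0.2, 0.3, 1)
    magn_m <- dir_m %*% t(cbind(0.15 * trem + drift)) + c(20, 0, 40) +
      noise(0.3)

    sensors <- list(
      acce = triaxial_series(acce_m[1, ], acce_m[2, ], acce_m[3, ], fs),
      gyro = triaxial_series(gyro_m[1, ], gyro_m[2, ], gyro_m[3, ], fs),
      magn = triaxial_series(magn_m[1, ], magn_m[2, ], magn_m[3, ], fs))
    recording_session(patient_params$patient_id, exercise, state, sensors)
  })
}

#' Generate a full synthetic cohort
#'
#' Simulates every patient in both medication states for all four
#' exercises. Session seeds are derived deterministically from the
#' config seed, so cohorts are reproducible bit for bit.
#'
#' @param cfg A [sim_config()].
#' @param exercises Which exercises to simulate (default 0:3).
#' @return A `simulated_cohort`: list with `sessions` (list of
#'   [recording_session()]), `truth` (patient parameter data frame) and
#'   `config`.
#' @export
generate_cohort <- function(cfg = sim_config(), exercises = 0:3) {
  truth <- draw_patient_params(cfg)
  sessions <- list()
  for (p in seq_len(nrow(truth))) {
    for (ex in exercises) {
      for (state in c("OFF", "ON")) {
        sseed <- derive_seed(cfg$seed + 1000L * p + 10L * ex +
                               (state == "ON"), "session")
        sessions[[length(sessions) + 1L]] <-
          simulate_session(truth[p, ], ex, state, cfg, seed = sseed)
      }
    }
  }
  structure(list(sessions = sessions, truth = truth, config = cfg),
            class = "simulated_cohort")
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf("simulated_cohort: %d patients, %d sessions\n",
              nrow(x$truth), length(x$sessions)))
  invisible(x)
}

#' Subset the sessions of a cohort by exercise
#'
#' @param cohort A `simulated_cohort`.
#' @param exercise Integer exercise id.
#' @return List of [recording_session()] objects.
#' @export
cohort_sessions <- function(cohort, exercise) {
  Filter(function(s) s$exercise == exercise, cohort$sessions)
}
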