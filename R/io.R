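#' Write and read recording sessions as long-form CSV
#'
#' One row per time sample per sensor, columns `patient_id, exercise,
#' state, sensor, t_index, x, y, z`. The dialect is fixed: UTF-8,
#' comma-separated, `.` decimal point, independent of locale.
#'
#' @param sessions List of [recording_session()] objects.
#' @param path Output CSV path.
#' @param fs Sampling rate recorded in the sessions (used on read).
#' @return `write_sessions_csv` returns `path` invisibly;
#'   `read_sessions_csv` returns a list of sessions.
#' @export
write_sessions_csv <- function(sessions, path) {
  rows <- lapply(sessions, function(s) {
    do.call(rbind, lapply(sensor_names(), function(sn) {
      ser <- s$sensors[[sn]]
      data.frame(patient_id = s$patient_id, exercise = s$exercise,
                 state = s$state, sensor = sn,
                 t_index = seq_along(ser$x) - 1L,
                 x = ser$x, y = ser$y, z = ser$z,
                 stringsAsFactors = FALSE)
    }))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sessions_csv
#' @export
read_sessions_csv <- function(path, fs = 100) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "exercise", "state", "sensor", "t_index",
            "x", "y", "z")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("session CSV is missing columns: ", paste(missing, collapse = ", "))
  }
  key <- interaction(df$patient_id, df$exercise, df$state, drop = TRUE)
  lapply(split(df, key), function(d) {
    sensors <- lapply(split(d, d$sensor), function(sd) {
      sd <- sd[order(sd$t_index), ]
      triaxial_series(sd$x, sd$y, sd$z, fs)
    })
    recording_session(d$patient_id[1], d$exercise[1], d$state[1], sensors)
  })
}

#' Write and read feature matrices as CSV
#'
#' Header row of feature names, one row per window, with trailing
#' columns `label`, `patient_id`, `window_index`. Round-trips values to
#' better than 1e-12 and preserves column order.
#'
#' @param fm A [feature_matrix()].
#' @param path CSV path.
#' @return `write_feature_matrix` returns `path` invisibly;
#'   `read_feature_matrix` returns a [feature_matrix()].
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- as.data.frame(fm$features)
  df$label <- fm$labels
  df$patient_id <- fm$meta$patient_id
  df$window_index <- fm$meta$window_index
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE)
  if (anyDuplicated(names(df))) {
    stop("duplicated column names in ", path)
  }
  if (!"label" %in% names(df)) stop("feature CSV lacks a 'label' column")
  tail_cols <- intersect(c("label", "patient_id", "window_index"),
                         names(df))
  feat_cols <- setdiff(names(df), tail_cols)
  X <- as.matrix(df[, feat_cols, drop = FALSE])
  if (!is.numeric(X)) {
    bad <- feat_cols[!vapply(df[feat_cols], is.numeric, logical(1))]
    stop("non-numeric feature columns: ", paste(bad, collapse = ", "))
  }
  meta <- data.frame(
    patient_id = if ("patient_id" %in% names(df)) df$patient_id
                 else rep(NA_character_, nrow(df)),
    window_index = if ("window_index" %in% names(df)) df$window_index
                   else seq_len(nrow(df)) - 1L,
    state = ifelse(df$label == 1L, "ON", "OFF"),
    stringsAsFactors = FALSE)
  feature_matrix(X, df$label, meta)
}

default_config_keys <- list(
  sampling = c("fs_hz"),
  window = c("length_samples", "step_samples"),
  scoring = c("epsilon", "weight_ttest", "weight_rf", "weight_pca",
              "n_trees", "retention_fraction"),
  fc = c("generations", "population", "selection_rate", "mutation_rate",
         "n_features", "chromosome_length", "codon_bound",
         "tournament_size", "rbf_nodes", "max_wraps"),
  eval = c("folds", "repeats", "hidden_nodes", "pca_components",
           "group_by_patient"),
  sim = c("n_patients", "duration_s", "tremor_band", "tremor_amp_off",
          "tremor_amp_on", "jitter_off", "jitter_on", "tap_rate_off",
          "tap_rate_on", "noise_sd")
)

#' Default pipeline configuration
#'
#' Nested list of the per-stage configuration blocks with the package
#' defaults (window 100/50 samples at 100 Hz, scoring weights
#' 0.4/0.3/0.3 with 80% retention, GA with 500 generations x 500
#' chromosomes, 10-fold CV with 30 repeats).
#'
#' @param seed Global pipeline seed.
#' @param exercises Exercises processed by [run_pipeline()].
#' @return Nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1L, exercises = 0:3) {
  list(
    seed = as.integer(seed),
    exercises = as.integer(exercises),
    sampling = list(fs_hz = 100),
    window = list(length_samples = 100L, step_samples = 50L),
    scoring = list(epsilon = 1e-10, weight_ttest = 0.4, weight_rf = 0.3,
                   weight_pca = 0.3, n_trees = 200L,
                   retention_fraction = 0.8),
    fc = list(generations = 500L, population = 500L, selection_rate = 0.10,
              mutation_rate = 0.05, n_features = 3L,
              chromosome_length = 100L, codon_bound = 255L,
              tournament_size = 4L, rbf_nodes = 10L, max_wraps = 2L),
    eval = list(folds = 10L, repeats = 30L, hidden_nodes = 10L,
                pca_components = 2L, group_by_patient = FALSE),
    sim = list(n_patients = 14L, duration_s = c(10, 13, 16, 12),
               tremor_band = c(4, 6), tremor_amp_off = 1.0,
               tremor_amp_on = 0.4, jitter_off = 0.3, jitter_on = 0.1,
               tap_rate_off = 1.5, tap_rate_on = 2.5, noise_sd = 0.05)
  )
}

#' Read a pipeline configuration file
#'
#' YAML file with the blocks of [default_pipeline_config()]; supplied
#' values override the defaults, unknown keys are rejected with the
#' offending name.
#'
#' @param path YAML config path.
#' @return Validated nested configuration list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_pipeline_config()
  top_known <- c("seed", "exercises", names(default_config_keys))
  unknown <- setdiff(names(user), top_known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  for (blk in names(user)) {
    if (blk %in% c("seed", "exercises")) {
      cfg[[blk]] <- user[[blk]]
      next
    }
    bad <- setdiff(names(user[[blk]]), default_config_keys[[blk]])
    if (length(bad)) {
      stop("unknown config key(s) in block '", blk, "': ",
           paste(bad, collapse = ", "))
    }
    cfg[[blk]][names(user[[blk]])] <- user[[blk]]
  }
  cfg
}

config_to_objects <- function(cfg) {
  list(
    window = window_spec(cfg$window$length_samples, cfg$window$step_samples),
    scoring = scoring_config(epsilon = cfg$scoring$epsilon,
                             weight_ttest = cfg$scoring$weight_ttest,
                             weight_rf = cfg$scoring$weight_rf,
                             weight_pca = cfg$scoring$weight_pca,
                             n_trees = cfg$scoring$n_trees,
                             retention_fraction = cfg$scoring$retention_fraction,
                             seed = derive_seed(cfg$seed, "score")),
    fc = fc_config(generations = cfg$fc$generations,
                   population = cfg$fc$population,
                   selection_rate = cfg$fc$selection_rate,
                   mutation_rate = cfg$fc$mutation_rate,
                   n_features = cfg$fc$n_features,
                   chromosome_length = cfg$fc$chromosome_length,
                   codon_bound = cfg$fc$codon_bound,
                   tournament_size = cfg$fc$tournament_size,
                   rbf_nodes = cfg$fc$rbf_nodes,
                   max_wraps = cfg$fc$max_wraps,
                   seed = derive_seed(cfg$seed, "construct")),
    eval = eval_config(folds = cfg$eval$folds, repeats = cfg$eval$repeats,
                       hidden_nodes = cfg$eval$hidden_nodes,
                       pca_components = cfg$eval$pca_components,
                       group_by_patient = cfg$eval$group_by_patient,
                       seed = derive_seed(cfg$seed, "evaluate")),
    sim = sim_config(n_patients = cfg$sim$n_patients, fs = cfg$sampling$fs_hz,
                     duration_s = cfg$sim$duration_s,
                     tremor_band = cfg$sim$tremor_band,
                     tremor_amp_off = cfg$sim$tremor_amp_off,
                     tremor_amp_on = cfg$sim$tremor_amp_on,
                     jitter_off = cfg$sim$jitter_off,
                     jitter_on = cfg$sim$jitter_on,
                     tap_rate_off = cfg$sim$tap_rate_off,
                     tap_rate_on = cfg$sim$tap_rate_on,
                     noise_sd = cfg$sim$noise_sd,
                     seed = derive_seed(cfg$seed, "simulate"))
  )
}

#' Run the full pipeline on a synthetic cohort
#'
#' Chains simulation, feature extraction, composite scoring with
#' top-80% retention, grammatical-evolution feature construction and
#' cross-validated evaluation (constructed features vs the raw-feature
#' RBF baseline) for each requested exercise. Artifacts (scores CSV,
#' feature CSVs, constructed-expression manifest, report CSV) are
#' written into `out_dir` when supplied.
#'
#' @param cfg Nested configuration list (see
#'   [default_pipeline_config()]).
#' @param out_dir Optional output directory for artifacts.
#' @param methods Model specifications to evaluate besides the
#'   feature-construction method; default the raw-feature RBF baseline.
#' @return List of per-exercise results: `scores`, `retained`,
#'   `constructed` (expressions + fitness trace), and `reports` (one
#'   `evaluation_report` per method).
#' @export
run_pipeline <- function(cfg = default_pipeline_config(), out_dir = NULL,
                         methods = list(method_rbf())) {
  obj <- config_to_objects(cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }
  cohort <- generate_cohort(obj$sim, exercises = cfg$exercises)
  results <- list()
  report_rows <- list()
  for (ex in cfg$exercises) {
    gefc_log("exercise %d: extracting features", ex)
    fm <- extract_feature_matrix(cohort_sessions(cohort, ex), obj$window)
    scores <- score_features(fm, obj$scoring)
    retained <- select_top_features(scores, obj$scoring)
    fm_sel <- feature_matrix(fm$features[, retained, drop = FALSE],
                             fm$labels, fm$meta, fm$exercise)
    fc_method <- method_fc(obj$fc)
    reports <- list()
    for (m in c(methods, list(fc_method))) {
      gefc_log("exercise %d: evaluating %s", ex, m$name)
      reports[[m$name]] <- crossval_evaluate(fm_sel, m, obj$eval)
    }
    constructed <- evolve_features(fm_sel$features, fm_sel$labels, obj$fc)
    res <- list(exercise = ex, scores = scores, retained = retained,
                constructed = constructed, reports = reports)
    results[[paste0("exercise", ex)]] <- res
    for (m in names(reports)) {
      report_rows[[length(report_rows) + 1L]] <- data.frame(
        exercise = ex, method = m,
        error = reports[[m]]$error,
        precision = reports[[m]]$precision,
        recall = reports[[m]]$recall,
        auroc = reports[[m]]$auroc)
    }
    if (!is.null(out_dir)) {
      write_feature_matrix(fm, file.path(out_dir,
                                         sprintf("features_ex%d.csv", ex)))
      sc <- scores
      sc$exercise <- ex
      utils::write.csv(sc, file.path(out_dir,
                                     sprintf("scores_ex%d.csv", ex)),
                       row.names = FALSE)
      writeLines(constructed$strings,
                 file.path(out_dir, sprintf("expressions_ex%d.txt", ex)))
    }
  }
  report <- do.call(rbind, report_rows)
  if (!is.null(out_dir)) {
    utils::write.csv(report, file.path(out_dir, "report.csv"),
                     row.names = FALSE)
    manifest <- list(seed = cfg$seed, exercises = cfg$exercises,
                     config = cfg,
                     expressions = lapply(results, function(r)
                       r$constructed$strings))
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  structure(list(results = results, report = report, config = cfg),
            class = "gefc_pipeline_result")
}

#' @export
print.gefc_pipeline_result <- function(x, ...) {
  cat("gefc pipeline result\n")
  print(x$report)
  invisible(x)
}
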