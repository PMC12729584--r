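#' Scoring configuration
#'
#' Parameters of the tripartite composite feature-ranking scheme:
#' t-test, random-forest Gini importance and PCA loading scores are
#' min-max normalised and combined with weights 0.4 / 0.3 / 0.3; the
#' top `retention_fraction` of features by composite score is retained.
#'
#' @param epsilon Small constant inside the t-test log transform
#'   (default 1e-10), guarding against p = 0.
#' @param weight_ttest,weight_rf,weight_pca Non-negative weights
#'   summing to 1 (defaults 0.4, 0.3, 0.3).
#' @param n_trees Random-forest size (default 200).
#' @param retention_fraction Fraction of features kept (default 0.8).
#' @param seed Integer seed for the random forest.
#' @return An object of class `scoring_config`.
#' @export
scoring_config <- function(epsilon = 1e-10, weight_ttest = 0.4,
                           weight_rf = 0.3, weight_pca = 0.3,
                           n_trees = 200L, retention_fraction = 0.8,
                           seed = 1L) {
  w <- c(weight_ttest, weight_rf, weight_pca)
  if (any(w < 0) || abs(sum(w) - 1) > 1e-9) {
    stop("weights must be non-negative and sum to 1")
  }
  if (epsilon <= 0) stop("epsilon must be positive")
  if (retention_fraction <= 0 || retention_fraction > 1) {
    stop("retention_fraction must be in (0, 1]")
  }
  structure(list(epsilon = epsilon, weight_ttest = weight_ttest,
                 weight_rf = weight_rf, weight_pca = weight_pca,
                 n_trees = as.integer(n_trees),
                 retention_fraction = retention_fraction,
                 seed = as.integer(seed)),
            class = "scoring_config")
}

#' Paired t-test feature score
#'
#' The p-value of a t-test between OFF and ON measurements is mapped to
#' `-log10(p + epsilon)`, so strongly significant features get large
#' scores while the small constant caps the score at
#' `-log10(epsilon)` (10 at the default) when p underflows to zero.
#' When `pairing` (patient ids for both groups) is supplied, values are
#' first aggregated to per-patient means per state and a paired t-test
#' is run; otherwise Welch's unpaired test is used.
#'
#' @param off_values,on_values Numeric vectors of the feature in each
#'   state.
#' @param pairing Optional list with elements `off` and `on`: patient
#'   ids aligned with the value vectors.
#' @param cfg A [scoring_config()].
#' @return Scalar score.
#' @export
ttest_score <- function(off_values, on_values, pairing = NULL,
                        cfg = scoring_config()) {
  stopifnot(length(off_values) > 0L, length(on_values) > 0L)
  if (!is.null(pairing)) {
    m_off <- tapply(off_values, pairing$off, mean)
    m_on <- tapply(on_values, pairing$on, mean)
    ids <- sort(names(m_off))
    if (!identical(ids, sort(names(m_on)))) {
      stop("paired t-test requires matching patient sets in both states")
    }
    a <- as.numeric(m_off[ids])
    b <- as.numeric(m_on[ids])
    if (max(abs(a - b)) < 1e-300 || stats::sd(a - b) == 0) {
      # degenerate paired differences: constant difference vector
      p <- if (all(a == b)) 1 else 0
    } else {
      p <- stats::t.test(a, b, paired = TRUE)$p.value
    }
  } else {
    gefc_log("no pairing supplied; using Welch's unpaired t-test")
    if (stats::sd(off_values) == 0 && stats::sd(on_values) == 0) {
      p <- if (mean(off_values) == mean(on_values)) 1 else 0
    } else {
      p <- stats::t.test(off_values, on_values, paired = FALSE)$p.value
    }
  }
  -log10(p + cfg$epsilon)
}

#' Random-forest Gini importance
#'
#' Mean decrease in Gini impurity of each feature over an ensemble of
#' `cfg$n_trees` classification trees separating OFF from ON windows,
#' i.e. the impurity reduction summed over the nodes a feature splits,
#' averaged across trees. Deterministic given `cfg$seed`.
#'
#' @param fm A [feature_matrix()].
#' @param cfg A [scoring_config()].
#' @param ... Further arguments passed to
#'   [randomForest::randomForest()] (e.g. `replace`, `sampsize`).
#' @return Named numeric vector of non-negative importances.
#' @export
rf_gini_importance <- function(fm, cfg = scoring_config(), ...) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (length(unique(fm$labels)) < 2L) {
    stop("both classes must be present for importance")
  }
  y <- factor(fm$labels, levels = c(0L, 1L))
  imp <- with_local_seed(cfg$seed, {
    rf <- randomForest::randomForest(x = fm$features, y = y,
                                     ntree = cfg$n_trees,
                                     importance = FALSE, ...)
    randomForest::importance(rf, type = 2)
  })
  out <- imp[, 1]
  names(out) <- colnames(fm$features)
  out
}

#' PCA loading score
#'
#' Columns are standardised and decomposed by PCA; the loading of a
#' feature on a component is its correlation with that component
#' (eigenvector entry scaled by the component standard deviation), and
#' the score is the sum of absolute loadings over all components with
#' eigenvalue above 1e-12. Zero-variance columns score 0.
#'
#' @param fm A [feature_matrix()].
#' @return Named numeric vector of scores.
#' @export
pca_loading_score <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  X <- fm$features
  if (nrow(X) < 2L) stop("need at least 2 rows for PCA")
  sds <- apply(X, 2, stats::sd)
  keep <- sds > 0
  out <- stats::setNames(rep(0, ncol(X)), colnames(X))
  if (!any(keep)) return(out)
  if (any(!keep)) gefc_log("%d zero-variance columns scored 0", sum(!keep))
  pc <- stats::prcomp(X[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2
  comp <- ev > 1e-12
  loadings <- pc$rotation[, comp, drop = FALSE] %*% diag(pc$sdev[comp],
                                                         nrow = sum(comp))
  out[colnames(X)[keep]] <- rowSums(abs(loadings))
  out
}

minmax_normalize <- function(v) {
  rng <- range(v)
  if (diff(rng) == 0) {
    gefc_log("constant raw score vector normalised to all-0")
    return(rep(0, length(v)))
  }
  (v - rng[1]) / diff(rng)
}

#' Composite feature scores
#'
#' Each of the three raw score vectors is min-max normalised
#' independently, then combined as
#' `0.4 * ttest + 0.3 * rf + 0.3 * pca` (weights from `cfg`). Ranks are
#' assigned by descending composite score with ties broken by ascending
#' feature name. A constant raw vector normalises to all zeros.
#'
#' @param raw Data frame with columns `feature_name`, `score_ttest`,
#'   `score_rf`, `score_pca`.
#' @param cfg A [scoring_config()].
#' @return Data frame adding `norm_*`, `composite` and `rank` columns,
#'   sorted by rank.
#' @export
composite_scores <- function(raw, cfg = scoring_config()) {
  stopifnot(nrow(raw) >= 2L)
  raw$norm_ttest <- minmax_normalize(raw$score_ttest)
  raw$norm_rf <- minmax_normalize(raw$score_rf)
  raw$norm_pca <- minmax_normalize(raw$score_pca)
  raw$composite <- cfg$weight_ttest * raw$norm_ttest +
    cfg$weight_rf * raw$norm_rf + cfg$weight_pca * raw$norm_pca
  ord <- order(-raw$composite, raw$feature_name)
  raw <- raw[ord, , drop = FALSE]
  raw$rank <- seq_len(nrow(raw))
  rownames(raw) <- NULL
  raw
}

#' Retain the top fraction of features
#'
#' Keeps the best `max(1, floor(retention_fraction * n))` features by
#' composite score (ties by ascending name, as in
#' [composite_scores()]).
#'
#' @param scored Data frame from [composite_scores()].
#' @param cfg A [scoring_config()].
#' @return Character vector of retained feature names, best first.
#' @export
select_top_features <- function(scored, cfg = scoring_config()) {
  stopifnot(nrow(scored) >= 1L)
  n_keep <- max(1L, floor(cfg$retention_fraction * nrow(scored)))
  ord <- order(-scored$composite, scored$feature_name)
  scored$feature_name[ord][seq_len(n_keep)]
}

#' Score all features of a matrix
#'
#' Runs the three scorers over every column of a feature matrix and
#' combines them into composite scores. The t-test pairs per-patient
#' means when patient ids are available in the metadata (and every
#' patient has windows in both states); otherwise it falls back to
#' Welch's test.
#'
#' @param fm A [feature_matrix()].
#' @param cfg A [scoring_config()].
#' @return Data frame of per-feature score breakdowns (one row per
#'   feature, ranked).
#' @export
score_features <- function(fm, cfg = scoring_config()) {
  stopifnot(inherits(fm, "feature_matrix"))
  off <- fm$labels == 0L
  pid <- fm$meta$patient_id
  paired <- !anyNA(pid) &&
    setequal(unique(pid[off]), unique(pid[!off])) &&
    length(unique(pid[off])) >= 2L
  t_scores <- vapply(seq_len(ncol(fm$features)), function(j) {
    v <- fm$features[, j]
    pr <- if (paired) list(off = pid[off], on = pid[!off]) else NULL
    ttest_score(v[off], v[!off], pairing = pr, cfg = cfg)
  }, numeric(1))
  rf_scores <- rf_gini_importance(fm, cfg)
  pca_scores <- pca_loading_score(fm)
  raw <- data.frame(feature_name = colnames(fm$features),
                    score_ttest = t_scores,
                    score_rf = as.numeric(rf_scores),
                    score_pca = as.numeric(pca_scores),
                    stringsAsFactors = FALSE)
  composite_scores(raw, cfg)
}
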