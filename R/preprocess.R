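#' Preprocessing configuration
#'
#' Parameters of the fixed preprocessing chain applied to each platform:
#' missingness filtering, half-minimum imputation of below-detection-limit
#' values, chained-equations multiple imputation of covariates, outlier
#' truncation, and QC-anchored loess drift normalisation.
#'
#' @param missing_threshold Features with missing fraction strictly greater
#'   than this (among study samples) are removed; the boundary is kept.
#'   Default 0.20.
#' @param iqr_multiplier Values are truncated to within `iqr_multiplier`
#'   interquartile ranges of the first and third quartiles. Default 3.
#' @param loess_span Span of the loess fit of QC intensity against run order
#'   within each batch. Default 0.75. Applied to LC-MS- and GC-MS-type
#'   platforms only.
#' @param loess_platforms Platforms that receive loess normalisation.
#' @param m Number of multiply imputed datasets (default 10).
#' @param mice_iterations Burn-in sweeps of the chained equations per
#'   imputation (default 10).
#' @param imputation_seed Seed for the imputation chains.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(missing_threshold = 0.20,
                              iqr_multiplier = 3,
                              loess_span = 0.75,
                              loess_platforms = c("lcms", "gcms"),
                              m = 10L,
                              mice_iterations = 10L,
                              imputation_seed = 1L) {
  if (missing_threshold <= 0 || missing_threshold >= 1)
    abort("missing_threshold must be in (0, 1)")
  if (iqr_multiplier <= 0) abort("iqr_multiplier must be positive")
  if (loess_span <= 0 || loess_span > 1) abort("loess_span must be in (0, 1]")
  if (m < 2) abort("m must be at least 2")
  structure(list(missing_threshold = missing_threshold,
                 iqr_multiplier = iqr_multiplier,
                 loess_span = loess_span,
                 loess_platforms = loess_platforms,
                 m = as.integer(m),
                 mice_iterations = as.integer(mice_iterations),
                 imputation_seed = as.integer(imputation_seed)),
            class = "preprocess_config")
}

meta_cols <- c("sample_id", "batch", "run_order", "is_qc")

feature_cols <- function(data) setdiff(names(data), meta_cols)

check_feature_table <- function(data) {
  missing <- setdiff(meta_cols, names(data))
  if (length(missing))
    abort(sprintf("feature table lacks metadata columns: %s",
                  paste(missing, collapse = ", ")))
  invisible(data)
}

#' Remove features with excess missingness
#'
#' Drops feature columns whose missing fraction among study (non-QC) samples
#' exceeds `threshold`. Features at exactly the threshold are kept. Column
#' order is preserved.
#'
#' @param data A feature table (metadata columns `sample_id`, `batch`,
#'   `run_order`, `is_qc`, then feature columns).
#' @param threshold Maximum tolerated missing fraction, in (0, 1).
#' @return The feature table with offending columns removed; the dropped
#'   names are recorded in attribute `dropped`.
#' @export
filter_missingness <- function(data, threshold = 0.20) {
  check_feature_table(data)
  if (threshold <= 0 || threshold >= 1) abort("threshold must be in (0, 1)")
  feats <- feature_cols(data)
  study <- data[!data$is_qc, feats, drop = FALSE]
  frac <- vapply(study, function(x) mean(is.na(x)), numeric(1))
  drop <- feats[frac > threshold]
  if (length(drop) == length(feats))
    abort("all features exceed the missingness threshold")
  out <- data[, c(meta_cols, setdiff(feats, drop)), drop = FALSE]
  attr(out, "dropped") <- drop
  out
}

#' Impute below-detection-limit values as half the minimum nonzero value
#'
#' Every missing entry of a feature becomes 0.5 times the minimum nonzero
#' observed value of that feature; observed entries are untouched. Intended
#' for metabolite matrices where missingness means censoring below the
#' detection limit.
#'
#' @param data A feature table.
#' @return The completed feature table.
#' @export
impute_half_min <- function(data) {
  check_feature_table(data)
  for (j in feature_cols(data)) {
    x <- data[[j]]
    miss <- is.na(x)
    if (!any(miss)) next
    obs <- x[!miss & x != 0]
    if (length(obs) == 0)
      abort(sprintf("feature '%s' has no nonzero observed value to anchor imputation", j))
    x[miss] <- 0.5 * min(obs)
    data[[j]] <- x
  }
  data
}

#' Truncate outliers to within a multiple of the interquartile range
#'
#' Values are clipped to `[Q1 - k * IQR, Q3 + k * IQR]` where Q1 and Q3 are
#' the first and third quartiles (type-7 quantiles) and `k` is
#' `iqr_multiplier`. Constant variables are returned unchanged. The
#' operation is idempotent: as long as fewer than a quarter of the values are
#' clipped on each side, the quartiles of the clipped vector are unchanged.
#'
#' @param x A numeric vector, or a data frame whose numeric columns (other
#'   than the feature-table metadata columns) are each truncated.
#' @param iqr_multiplier Number of IQRs beyond the quartiles to allow.
#' @return Object of the same shape as `x`.
#' @export
truncate_outliers <- function(x, iqr_multiplier = 3) {
  if (is.data.frame(x)) {
    skip <- intersect(names(x), c(meta_cols, "participant_id", "case_status"))
    for (j in setdiff(names(x), skip)) {
      if (is.numeric(x[[j]])) x[[j]] <- truncate_outliers(x[[j]], iqr_multiplier)
    }
    return(x)
  }
  q <- quantile(x, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
  iqr <- q[2] - q[1]
  if (iqr == 0) return(x)
  pmin(pmax(x, q[1] - iqr_multiplier * iqr), q[2] + iqr_multiplier * iqr)
}

#' Normalise within-batch signal drift against pooled QC samples
#'
#' Per batch and feature, a loess curve of log QC intensity against run order
#' is fit (span `span`, quadratic local fits, direct surface so study run
#' orders beyond the QC range extrapolate), and every sample's value is
#' divided by the curve's prediction at its run order, then rescaled by the
#' batch QC median so units are preserved. Batches with fewer than
#' `min_qc` QC rows fall back to median scaling (values scaled by the ratio
#' of the overall QC median to the batch QC median), recorded in attribute
#' `fallback_batches`.
#'
#' @param data A complete (no missing values) feature table.
#' @param span Loess span (default 0.75).
#' @param min_qc Minimum QC rows per batch for a loess fit (default 4).
#' @return The normalised feature table.
#' @export
loess_normalize <- function(data, span = 0.75, min_qc = 4L) {
  check_feature_table(data)
  feats <- feature_cols(data)
  if (anyNA(data[, feats])) abort("loess_normalize requires a complete matrix; impute first")
  batches <- unique(data$batch)
  fallback <- character()
  # reference medians are taken from the input, never from partially
  # normalised data, so the transform is well-defined and idempotent
  overall_med <- vapply(feats, function(j) median(data[[j]][data$is_qc]),
                        numeric(1))
  for (b in batches) {
    rows <- which(data$batch == b)
    qc_rows <- rows[data$is_qc[rows]]
    if (length(qc_rows) < min_qc) {
      fallback <- c(fallback, as.character(b))
      if (length(qc_rows) == 0) next
      for (j in feats) {
        batch_med <- median(data[[j]][qc_rows])
        if (batch_med <= 0) next
        data[[j]][rows] <- data[[j]][rows] * (overall_med[[j]] / batch_med)
      }
      next
    }
    t_qc <- data$run_order[qc_rows]
    t_all <- data$run_order[rows]
    for (j in feats) {
      lq <- log(data[[j]][qc_rows])
      fit <- stats::loess(lq ~ t_qc, span = span, degree = 2,
                          family = "gaussian",
                          control = stats::loess.control(surface = "direct"))
      pred <- predict(fit, newdata = data.frame(t_qc = t_all))
      med <- median(data[[j]][qc_rows])
      data[[j]][rows] <- exp(log(data[[j]][rows]) - pred + log(med))
    }
  }
  if (length(fallback))
    inform(sprintf("loess_normalize: median-scaling fallback in batch(es) %s (fewer than %d QC rows)",
                   paste(fallback, collapse = ", "), min_qc))
  attr(data, "fallback_batches") <- fallback
  data
}

#' Median coefficient of variation across replicate QC samples
#'
#' Computes, per feature, the percent coefficient of variation
#' (100 * SD / mean) over designated replicate rows, and summarises a
#' platform by the median over features. Features with non-positive mean are
#' excluded (recorded in the output).
#'
#' @param data A feature table.
#' @param replicate_ids Optional character vector of `sample_id`s to treat as
#'   replicates; defaults to all QC rows.
#' @return A list of class `qc_summary`: `median_cv` (percent), `per_feature`
#'   (tibble of feature CVs), `n_replicates`, `excluded` (features skipped).
#' @export
qc_median_cv <- function(data, replicate_ids = NULL) {
  check_feature_table(data)
  rows <- if (is.null(replicate_ids)) which(data$is_qc) else
    which(data$sample_id %in% replicate_ids)
  if (length(rows) < 2) abort("need at least 2 replicate rows to compute a CV")
  feats <- feature_cols(data)
  cv <- vapply(feats, function(j) {
    x <- data[[j]][rows]
    x <- x[!is.na(x)]
    m <- mean(x)
    if (length(x) < 2 || m <= 0) return(NA_real_)
    100 * sd(x) / m
  }, numeric(1))
  excluded <- feats[is.na(cv)]
  per_feature <- tibble::tibble(feature = feats, cv_percent = unname(cv))
  structure(list(median_cv = median(cv, na.rm = TRUE),
                 per_feature = per_feature,
                 n_replicates = length(rows),
                 excluded = excluded),
            class = "qc_summary")
}

#' @export
print.qc_summary <- function(x, ...) {
  cat(sprintf("<qc_summary> median CV %.1f%% over %d features (%d replicates)\n",
              x$median_cv, sum(!is.na(x$per_feature$cv_percent)),
              x$n_replicates))
  invisible(x)
}

#' Run the fixed metabolite preprocessing chain for one platform
#'
#' Applies, in order: missingness filtering, half-minimum imputation,
#' outlier truncation, and (for platforms listed in
#' `config$loess_platforms`) QC-anchored loess normalisation. Covariate
#' multiple imputation is a cohort-level step and lives in
#' [impute_covariates_mice()].
#'
#' @param data A feature table.
#' @param platform Platform name, used to decide whether loess applies.
#' @param config A [preprocess_config()].
#' @return The preprocessed feature table.
#' @export
preprocess_platform <- function(data, platform, config = preprocess_config()) {
  out <- filter_missingness(data, config$missing_threshold)
  out <- impute_half_min(out)
  out <- truncate_outliers(out, config$iqr_multiplier)
  if (platform %in% config$loess_platforms) {
    out <- loess_normalize(out, span = config$loess_span)
  }
  out
}
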