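# Shared fixtures: all synthetic, built in code at test time.

# A small matched cohort: two platforms, dense QC coverage so loess fits are
# exercised (10 QCs per ~50-sample batch when qc_every = 5 and n_batches set).
tiny_cohort_config <- function(seed = 1, ...) {
  defaults <- list(
    n_cases_A = 40L, n_cases_B = 40L, n_controls = 80L,
    platform_sizes = c(lcms = 30L, nmr = 12L),
    n_signal_features = c(A = 0L, B = 5L),
    effect_size = 0.5,
    lod_missing_rate = c(lcms = 0.08, nmr = 0),
    drift_amplitude = c(lcms = 0.2, nmr = 0.02),
    tech_sd = c(lcms = 0.2, nmr = 0.03),
    qc_every = 5L, n_batches = 4L,
    seed = seed)
  do.call(cohort_config, utils::modifyList(defaults, list(...)))
}

# A light Super Learner library covering all three kinds, sized for tests.
sl_lib_small <- function() {
  sl_library(
    learner("elastic_net", params = list(alpha = 1, nfolds = 3)),
    learner("random_forest", params = list(num_trees = 40)),
    learner("boosted_trees", params = list(nrounds = 30)))
}

sl_lib_tiny <- function() {
  sl_library(
    learner("elastic_net", params = list(alpha = 1, nfolds = 3)),
    learner("random_forest", params = list(num_trees = 25)))
}

# A bare feature table with explicit values (one batch, qc rows optional).
toy_feature_table <- function(values, is_qc = rep(FALSE, nrow(values))) {
  values <- as.data.frame(values)
  dplyr::bind_cols(
    tibble::tibble(
      sample_id = ifelse(is_qc, sprintf("QC_%03d", seq_len(nrow(values))),
                         sprintf("S%03d", seq_len(nrow(values)))),
      batch = 1L,
      run_order = seq_len(nrow(values)),
      is_qc = is_qc),
    tibble::as_tibble(values))
}

# Logistic-model simulation used across learner tests.
sim_logistic <- function(n, p, beta, seed, names_prefix = "v") {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, sprintf("%s%02d", names_prefix, 1:p)))
    y <- rbinom(n, 1, plogis(drop(x %*% beta)))
    list(x = x, y = y)
  })
}
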