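#' Configuration for the synthetic matched case-control cohort
#'
#' Defines the study conditions the generator emulates: a 1:1 matched
#' case-control design nested in a cohort of post-menopausal women, with two
#' cancer outcomes (A, breast-like, the larger case series; B,
#' colorectal-like, the smaller), four metabolomics platforms with realistic
#' feature counts, interspersed pooled QC samples, multiplicative batch drift,
#' below-detection-limit censoring, and a sparse metabolite signal for one
#' outcome only.
#'
#' Platform defaults mirror a four-platform design: 150 serum LC-MS/MS
#' metabolites, 687 serum lipids, 59 urine NMR metabolites (complete, no
#' below-LOD censoring), and 107 identified urine GC-MS metabolites.
#' Per-platform technical noise standard deviations (log scale) are chosen so
#' the expected pooled-QC median coefficients of variation are about 20.7%,
#' 6.4%, 2.9% and 45.4% respectively, the precision ordering typical of these
#' technologies.
#'
#' @param n_cases_A,n_cases_B Case counts for the two outcomes (defaults 577
#'   and 181).
#' @param n_controls Number of matched controls retained, one per case; must
#'   equal `n_cases_A + n_cases_B`.
#' @param platform_sizes Named integer vector, platform -> feature count.
#' @param n_signal_features Named vector `c(A = , B = )`: number of truly
#'   associated metabolite features per outcome. Default: none for A, 10 for
#'   B, mirroring a null-signal / sparse-signal contrast.
#' @param effect_size Mean shift, in units of the total log-scale feature SD,
#'   applied to signal features in cases of the corresponding outcome.
#' @param signal_platform Platform carrying the signal features (default
#'   `"lcms"`).
#' @param covariate_missing_rates Named fractions of missing values injected
#'   into risk covariates (base covariates are always complete).
#' @param lod_missing_rate Named per-platform fraction of study values
#'   censored below the detection limit (lowest quantile per feature).
#' @param n_batches Number of analytical batches per platform; `NULL` means
#'   one batch per 27 study samples.
#' @param qc_every One pooled QC row is inserted after every `qc_every` study
#'   rows (default 9, i.e. 3 QCs per 27-sample batch).
#' @param drift_amplitude Named per-platform log-scale amplitude of
#'   within-batch intensity drift (a value of `log(2)` means a 2x drift across
#'   a batch).
#' @param drift_shape `"linear"` or `"quadratic"` within-batch drift on the
#'   log scale.
#' @param bio_sd Between-participant biological SD on the log scale.
#' @param tech_sd Named per-platform technical (replicate) SD on the log
#'   scale.
#' @param control_pool_factor Size of the eligible control pool relative to
#'   `n_controls`; the pool always contains one guaranteed-compatible control
#'   per case so matching is feasible.
#' @param seed Integer seed; all generator randomness derives from it.
#' @return An object of class `cohort_config` (a named list).
#' @export
cohort_config <- function(n_cases_A = 577L,
                          n_cases_B = 181L,
                          n_controls = n_cases_A + n_cases_B,
                          platform_sizes = c(lcms = 150L, lipid = 687L,
                                             nmr = 59L, gcms = 107L),
                          n_signal_features = c(A = 0L, B = 10L),
                          effect_size = 0.5,
                          signal_platform = "lcms",
                          covariate_missing_rates = c(
                            bmi = 0.005, waist = 0.005, smoking = 0.005,
                            energy_expend = 0.06, alcohol = 0.02,
                            calcium = 0.02, folate = 0.02, red_meat = 0.02),
                          lod_missing_rate = c(lcms = 0.08, lipid = 0.05,
                                               nmr = 0, gcms = 0.08),
                          n_batches = NULL,
                          qc_every = 9L,
                          drift_amplitude = c(lcms = 0.2, lipid = 0.05,
                                              nmr = 0.02, gcms = 0.3),
                          drift_shape = c("linear", "quadratic"),
                          bio_sd = 0.5,
                          tech_sd = c(lcms = 0.2048, lipid = 0.0639,
                                      nmr = 0.0290, gcms = 0.4329),
                          control_pool_factor = 1.5,
                          seed = 1L) {
  drift_shape <- match.arg(drift_shape)
  platforms <- names(platform_sizes)
  if (is.null(platforms) || anyDuplicated(platforms))
    abort("platform_sizes must be uniquely named")
  counts <- c(n_cases_A, n_cases_B, n_controls, platform_sizes, qc_every)
  if (any(counts <= 0)) abort("all counts must be positive")
  if (n_controls != n_cases_A + n_cases_B)
    abort("n_controls must equal the total number of cases (1:1 matching)")
  rates <- c(covariate_missing_rates, lod_missing_rate)
  if (any(rates < 0 | rates >= 1)) abort("rates must lie in [0, 1)")
  if (!signal_platform %in% platforms)
    abort(sprintf("signal_platform '%s' is not a platform", signal_platform))
  expand <- function(x) {
    if (length(x) == 1L && is.null(names(x))) x <- setNames(rep(x, length(platforms)), platforms)
    missing <- setdiff(platforms, names(x))
    if (length(missing)) abort(sprintf("missing per-platform value for: %s",
                                       paste(missing, collapse = ", ")))
    x[platforms]
  }
  cfg <- list(
    n_cases_A = as.integer(n_cases_A),
    n_cases_B = as.integer(n_cases_B),
    n_controls = as.integer(n_controls),
    platform_sizes = platform_sizes,
    n_signal_features = n_signal_features,
    effect_size = effect_size,
    signal_platform = signal_platform,
    covariate_missing_rates = covariate_missing_rates,
    lod_missing_rate = expand(lod_missing_rate),
    n_batches = n_batches,
    qc_every = as.integer(qc_every),
    drift_amplitude = expand(drift_amplitude),
    drift_shape = drift_shape,
    bio_sd = bio_sd,
    tech_sd = expand(tech_sd),
    control_pool_factor = control_pool_factor,
    seed = as.integer(seed)
  )
  structure(cfg, class = "cohort_config")
}

#' Matching rule for case-control pairing
#'
#' Cases are paired 1:1 to controls of the same self-identified
#' race/ethnicity, within `age_tolerance` years of age and
#' `enrollment_tolerance` months of enrollment date. The pairing minimises
#' the total tolerance-scaled distance `|age gap|/age_tolerance +
#' |enrollment gap|/enrollment_tolerance` over all feasible assignments.
#'
#' @param age_tolerance Maximum age gap in years (default 2).
#' @param enrollment_tolerance Maximum enrollment-date gap in months
#'   (default 2).
#' @return An object of class `match_rule`.
#' @export
match_rule <- function(age_tolerance = 2, enrollment_tolerance = 2) {
  if (age_tolerance <= 0 || enrollment_tolerance <= 0)
    abort("tolerances must be positive")
  structure(list(age_tolerance = age_tolerance,
                 enrollment_tolerance = enrollment_tolerance),
            class = "match_rule")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  cases: %d (A) + %d (B); matched controls: %d\n",
              x$n_cases_A, x$n_cases_B, x$n_controls))
  cat(sprintf("  platforms: %s\n",
              paste(sprintf("%s(%d)", names(x$platform_sizes),
                            x$platform_sizes), collapse = ", ")))
  cat(sprintf("  signal: %s features on %s, effect %.2f SD (A=%d, B=%d)\n",
              x$signal_platform, x$signal_platform, x$effect_size,
              x$n_signal_features[["A"]], x$n_signal_features[["B"]]))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
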