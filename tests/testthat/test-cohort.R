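test_that("a fixed seed reproduces the cohort exactly", {
  a <- generate_cohort(tiny_cohort_config(seed = 11))
  b <- generate_cohort(tiny_cohort_config(seed = 11))
  expect_identical(a$participants, b$participants)
  expect_identical(a$features, b$features)
  expect_identical(a$truth, b$truth)
  c <- generate_cohort(tiny_cohort_config(seed = 12))
  expect_false(identical(a$features$lcms, c$features$lcms))
})

test_that("default configuration carries the documented platform sizes", {
  cfg <- cohort_config()
  expect_equal(unname(cfg$platform_sizes),
               c(150L, 687L, 59L, 107L))
  expect_equal(cfg$n_cases_A + cfg$n_cases_B, cfg$n_controls)
})

test_that("full-size default cohort has the documented LC-MS feature count", {
  coh <- generate_cohort(cohort_config(seed = 1))
  expect_length(setdiff(names(coh$features$lcms),
                        c("sample_id", "batch", "run_order", "is_qc")), 150)
  expect_equal(nrow(coh$participants), 2 * 758)
  expect_true(all(check_pairing(coh$participants, coh$pairing)))
})

test_that("every case has exactly one matched control satisfying the rule", {
  coh <- generate_cohort(tiny_cohort_config(seed = 3))
  cases <- dplyr::filter(coh$participants, case_status != "control")
  expect_equal(nrow(coh$pairing), nrow(cases))
  expect_false(anyDuplicated(coh$pairing$control_id) > 0)
  expect_true(all(check_pairing(coh$participants, coh$pairing)))
  expect_setequal(cases$matched_control_id, coh$pairing$control_id)
})

test_that("covariate missingness tracks the configured rates", {
  cfg <- tiny_cohort_config(seed = 5, n_cases_A = 300L, n_cases_B = 300L,
                            n_controls = 600L,
                            covariate_missing_rates = c(energy_expend = 0.10,
                                                        bmi = 0.02))
  coh <- generate_cohort(cfg)
  n <- nrow(coh$participants)
  expect_equal(mean(is.na(coh$participants$energy_expend)), 0.10,
               tolerance = 0.35)
  expect_equal(mean(is.na(coh$participants$bmi)), 0.02, tolerance = 0.6)
  expect_false(anyNA(coh$participants$age))
  expect_false(anyNA(coh$participants$race_ethnicity))
})

test_that("below-LOD censoring removes exactly the lowest quantile per feature", {
  cfg0 <- tiny_cohort_config(seed = 7, lod_missing_rate = c(lcms = 0, nmr = 0))
  expect_false(anyNA(generate_cohort(cfg0)$features$lcms))

  rate <- 0.10
  cfg <- tiny_cohort_config(seed = 7, lod_missing_rate = c(lcms = rate, nmr = 0))
  f <- generate_cohort(cfg)$features$lcms
  study <- f[!f$is_qc, ]
  n_cens <- floor(rate * nrow(study))
  for (j in c("lcms_001", "lcms_017")) {
    expect_equal(sum(is.na(study[[j]])), n_cens)
    # censored entries are below every observed study value
    expect_false(anyNA(f[[j]][f$is_qc]))
  }
})

test_that("QC replicate CV% increases with the configured technical noise", {
  cvs <- vapply(c(0.05, 0.2, 0.45), function(s) {
    cfg <- tiny_cohort_config(seed = 9, tech_sd = c(lcms = s, nmr = 0.03),
                              drift_amplitude = c(lcms = 0, nmr = 0))
    qc_median_cv(generate_cohort(cfg)$features$lcms)$median_cv
  }, numeric(1))
  expect_true(all(diff(cvs) > 0))
  # drift-free CV tracks the lognormal noise CV, 100*sqrt(exp(s^2)-1)
  expect_equal(cvs[2], 100 * sqrt(exp(0.04) - 1), tolerance = 0.15)
})

test_that("a single signal feature attains the binormal oracle AUC", {
  # 1-SD log-scale mean shift => AUC = pnorm(1/sqrt(2)) ~ 0.760
  cfg <- cohort_config(
    n_cases_A = 25L, n_cases_B = 975L, n_controls = 1000L,
    platform_sizes = c(lcms = 5L),
    n_signal_features = c(A = 0L, B = 1L), effect_size = 1.0,
    lod_missing_rate = c(lcms = 0), drift_amplitude = c(lcms = 0),
    tech_sd = c(lcms = 0.2), seed = 21)
  coh <- generate_cohort(cfg)
  feat <- coh$truth$feature[1]
  f <- coh$features$lcms
  study <- f[!f$is_qc, ]
  st <- coh$participants$case_status[match(study$sample_id,
                                           coh$participants$participant_id)]
  use <- st %in% c("control", "case_B")
  emp <- auc(log(study[[feat]][use]), as.integer(st[use] == "case_B"))
  expect_equal(emp, pnorm(1 / sqrt(2)), tolerance = 0.045)

  # and with no effect the best single feature stays near chance
  cfg0 <- tiny_cohort_config(seed = 22, effect_size = 0,
                             n_cases_A = 100L, n_cases_B = 100L,
                             n_controls = 200L,
                             n_signal_features = c(A = 0L, B = 5L))
  coh0 <- generate_cohort(cfg0)
  f0 <- coh0$features$lcms
  study0 <- f0[!f0$is_qc, ]
  st0 <- coh0$participants$case_status[match(study0$sample_id,
                                             coh0$participants$participant_id)]
  use0 <- st0 %in% c("control", "case_B")
  a0 <- vapply(coh0$truth$feature, function(j) {
    auc(log(study0[[j]][use0]), as.integer(st0[use0] == "case_B"))
  }, numeric(1))
  expect_true(all(abs(a0 - 0.5) < 0.15))
})

test_that("truth annotations stay in the sidecar, never in the matrices", {
  coh <- generate_cohort(tiny_cohort_config(seed = 2))
  expect_true(all(c("platform", "feature", "outcome", "effect") %in%
                    names(coh$truth)))
  for (f in coh$features) {
    expect_named(f[1:4], c("sample_id", "batch", "run_order", "is_qc"))
  }
})
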