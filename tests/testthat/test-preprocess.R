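test_that("missingness filter drops strictly-above-threshold features only", {
  vals <- tibble::tibble(
    a = c(NA, NA, NA, 4:10),      # 3/10 missing -> dropped at 0.20
    b = c(NA, NA, 3:10),          # 2/10 missing -> kept (boundary)
    c = 1:10)
  tab <- toy_feature_table(vals)
  out <- filter_missingness(tab, 0.20)
  expect_setequal(setdiff(names(out), c("sample_id", "batch", "run_order", "is_qc")),
                  c("b", "c"))
  expect_equal(attr(out, "dropped"), "a")
})

test_that("QC rows are excluded from the missingness denominator", {
  vals <- tibble::tibble(a = c(NA, NA, 3, 4, 5, 6, 7, 8, 9, 10))
  # rows 3..10 are QC: only 2 study rows, both missing -> fraction 1
  tab <- toy_feature_table(vals, is_qc = c(rep(FALSE, 2), rep(TRUE, 8)))
  expect_error(filter_missingness(tab, 0.20), "all features")
})

test_that("random fixtures match an independent per-column missing recount", {
  for (seed in 1:5) {
    vals <- withr::with_seed(seed, {
      m <- matrix(runif(20 * 50), 20, 50)
      m[runif(length(m)) < 0.15] <- NA
      as.data.frame(m)
    })
    tab <- toy_feature_table(vals)
    out <- filter_missingness(tab, 0.20)
    kept_oracle <- names(vals)[colSums(is.na(vals)) / nrow(vals) <= 0.20]
    expect_identical(setdiff(names(out), c("sample_id", "batch", "run_order", "is_qc")),
                     kept_oracle)
  }
})

test_that("half-minimum imputation follows the stated rule exactly", {
  tab <- toy_feature_table(tibble::tibble(
    a = c(4, 2, NA, 5),
    b = c(0, 3, NA, 6),
    c = c(1, 2, 3, 4)))
  out <- impute_half_min(tab)
  expect_equal(out$a, c(4, 2, 1, 5))        # 0.5 * min = 0.5 * 2
  expect_equal(out$b, c(0, 3, 1.5, 6))      # minimum NONZERO is 3
  expect_equal(out$c, c(1, 2, 3, 4))        # no missing: identity
  bad <- toy_feature_table(tibble::tibble(z = c(0, 0, NA)))
  expect_error(impute_half_min(bad), "'z'")
})

test_that("IQR truncation clips to the stated bounds and is idempotent", {
  # Q1 = 10, Q3 = 20 -> bounds [-20, 50]
  x <- c(10, 10, 10, 15, 20, 20, 20, 60, -25)
  q <- quantile(x, c(.25, .75), names = FALSE)
  out <- truncate_outliers(x)
  expect_equal(max(out), q[2] + 3 * (q[2] - q[1]))
  expect_equal(min(out), q[1] - 3 * (q[2] - q[1]))
  expect_true(all(out[x >= q[1] - 3 * diff(q) & x <= q[2] + 3 * diff(q)] ==
                    x[x >= q[1] - 3 * diff(q) & x <= q[2] + 3 * diff(q)]))
  expect_identical(truncate_outliers(out), out)
  inside <- c(1, 2, 3, 4, 5)
  expect_identical(truncate_outliers(inside), inside)
  expect_identical(truncate_outliers(rep(7, 10)), rep(7, 10))
})

test_that("truncation matches a hand-computed type-7 quantile clip and never moves values away from the median", {
  for (seed in 1:5) {
    x <- withr::with_seed(seed, rt(200, df = 2) * 10)
    # independent type-7 quartiles: linear interpolation of order statistics
    manual_q <- function(p) {
      s <- sort(x); h <- (length(s) - 1) * p
      s[floor(h) + 1] + (h - floor(h)) * (s[floor(h) + 2 - (h == floor(h))] -
                                            s[floor(h) + 1])
    }
    lo <- manual_q(.25) - 3 * (manual_q(.75) - manual_q(.25))
    hi <- manual_q(.75) + 3 * (manual_q(.75) - manual_q(.25))
    out <- truncate_outliers(x)
    expect_equal(out, pmin(pmax(x, lo), hi), tolerance = 1e-12)
    med <- median(x)
    expect_true(all(abs(out - med) <= abs(x - med) + 1e-12))
  }
})

qc_cv_of <- function(tab) qc_median_cv(tab)$median_cv

test_that("loess normalisation leaves a drift-free batch unchanged and is deterministic", {
  vals <- withr::with_seed(1, tibble::tibble(
    a = exp(rnorm(30, 5, .3)), b = exp(rnorm(30, 7, .3))))
  is_qc <- seq_len(30) %% 5 == 0
  tab <- toy_feature_table(vals, is_qc = is_qc)
  # constant QC values: curve is flat at the median, study samples unchanged
  tab$a[is_qc] <- 20; tab$b[is_qc] <- 55
  out <- loess_normalize(tab)
  expect_equal(out$a[!is_qc], tab$a[!is_qc], tolerance = 1e-12)
  expect_equal(out$b[!is_qc], tab$b[!is_qc], tolerance = 1e-12)
  # two identical batches -> identical normalised outputs
  tab2 <- dplyr::bind_rows(tab, dplyr::mutate(
    tab, batch = 2L, run_order = run_order + 30L,
    sample_id = paste0(sample_id, "_b2")))
  out2 <- loess_normalize(tab2)
  expect_equal(out2$a[tab2$batch == 1], out2$a[tab2$batch == 2],
               tolerance = 1e-12)
})

test_that("loess removes generator-injected within-batch drift", {
  cfg <- tiny_cohort_config(seed = 31, drift_amplitude = c(lcms = log(2), nmr = 0),
                            drift_shape = "linear",
                            tech_sd = c(lcms = 0.05, nmr = 0.03),
                            lod_missing_rate = c(lcms = 0, nmr = 0))
  f <- generate_cohort(cfg)$features$lcms
  pre <- qc_cv_of(f)
  post <- qc_cv_of(loess_normalize(f))
  expect_lt(post, 0.5 * pre)
})

test_that("batches with too few QC rows fall back to median scaling", {
  vals <- withr::with_seed(2, tibble::tibble(a = exp(rnorm(40, 5, .2))))
  is_qc <- seq_len(40) %% 10 == 0   # 2 QCs per 20-row batch
  tab <- toy_feature_table(vals, is_qc = is_qc)
  tab$batch <- rep(1:2, each = 20)
  expect_message(out <- loess_normalize(tab), "fallback")
  expect_setequal(attr(out, "fallback_batches"), c("1", "2"))
  # batch medians of QC rows are aligned to the overall QC median
  med <- median(out$a[out$is_qc])
  for (b in 1:2) expect_equal(median(out$a[out$is_qc & out$batch == b]), med)
  # and the fallback is exactly idempotent
  out2 <- loess_normalize(out)
  expect_equal(out2$a, out$a, tolerance = 1e-12)
})

test_that("the preprocessing chain is a no-op on its own output when QC rows are noiseless", {
  # noiseless QC + quadratic drift: local quadratic regression reproduces the
  # drift exactly, so renormalising already-normalised data changes nothing
  cfg <- tiny_cohort_config(seed = 33, tech_sd = c(lcms = 0, nmr = 0),
                            drift_shape = "quadratic",
                            drift_amplitude = c(lcms = 0.4, nmr = 0),
                            lod_missing_rate = c(lcms = 0, nmr = 0))
  f <- generate_cohort(cfg)$features$lcms
  once <- loess_normalize(impute_half_min(filter_missingness(f)))
  twice <- loess_normalize(impute_half_min(filter_missingness(once)))
  expect_equal(as.data.frame(twice), as.data.frame(once), tolerance = 1e-10)
  # full chain including truncation is exactly idempotent without drift
  cfg0 <- tiny_cohort_config(seed = 34, tech_sd = c(lcms = 0, nmr = 0),
                             drift_amplitude = c(lcms = 0, nmr = 0),
                             lod_missing_rate = c(lcms = 0, nmr = 0))
  f0 <- generate_cohort(cfg0)$features$lcms
  p1 <- preprocess_platform(f0, "lcms")
  p2 <- preprocess_platform(p1, "lcms")
  expect_equal(as.data.frame(p2), as.data.frame(p1), tolerance = 1e-10)
})

test_that("QC median CV matches hand formulas and brute-force recomputation", {
  # identical replicates -> 0%
  tab <- toy_feature_table(tibble::tibble(a = rep(5, 6)),
                           is_qc = rep(TRUE, 6))
  expect_equal(qc_median_cv(tab)$median_cv, 0)
  # two replicates (9, 11): sd = sqrt(2), mean = 10
  tab2 <- toy_feature_table(tibble::tibble(a = c(9, 11)), is_qc = rep(TRUE, 2))
  expect_equal(qc_median_cv(tab2)$median_cv, 100 * sqrt(2) / 10)
  # 100-feature random fixture equals per-feature recomputation
  vals <- withr::with_seed(4, as.data.frame(matrix(exp(rnorm(8 * 100, 3, .4)),
                                                   8, 100)))
  tab3 <- toy_feature_table(vals, is_qc = rep(TRUE, 8))
  got <- qc_median_cv(tab3)
  oracle <- median(vapply(vals, function(x) 100 * sd(x) / mean(x), numeric(1)))
  expect_equal(got$median_cv, oracle, tolerance = 1e-12)
  # zero-mean features are excluded
  tab4 <- toy_feature_table(tibble::tibble(a = c(-1, 1), b = c(2, 4)),
                            is_qc = rep(TRUE, 2))
  expect_equal(qc_median_cv(tab4)$excluded, "a")
})
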