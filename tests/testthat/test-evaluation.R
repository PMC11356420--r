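test_that("the AUC matches hand values and the O(n^2) pairwise oracle", {
  expect_equal(auc(c(0.9, 0.1), c(1, 0)), 1)
  expect_equal(auc(rep(0.3, 10), rep(c(0, 1), 5)), 0.5)   # all ties
  pair_oracle <- function(s, y) {
    cases <- s[y == 1]; controls <- s[y == 0]
    total <- 0
    for (a in cases) for (b in controls) {
      total <- total + (a > b) + 0.5 * (a == b)
    }
    total / (length(cases) * length(controls))
  }
  for (seed in 1:20) {
    d <- withr::with_seed(seed, {
      s <- round(runif(200), 2)   # rounding forces ties
      y <- rbinom(200, 1, 0.4)
      list(s = s, y = y)
    })
    if (length(unique(d$y)) < 2) next
    expect_equal(auc(d$s, d$y), pair_oracle(d$s, d$y), tolerance = 1e-12)
  }
  expect_error(auc(c(1, 2), c(1, 1)), "degenerate")
})

test_that("a perfectly separating covariate attains CV-AUC 1", {
  y <- rep(c(0, 1), each = 30)
  d <- tibble::tibble(outcome = y, sep = y * 10 + seq_along(y) / 1000,
                      noise = withr::with_seed(1, rnorm(60)))
  r <- cv_evaluate(d, "lasso_GLM", reps = 3, folds = 3, seed = 1)
  expect_equal(r$mean_auc, 1)
})

test_that("procedure specs validate their structure", {
  expect_length(standard_procedures(), 6)
  sp <- procedure_spec("SL_screens")
  expect_equal(sp$selector, "none")
  expect_true(sp$screens)
  expect_error(procedure_spec("nonsense"))
})

test_that("replicate AUCs are stable under doubling the replication count", {
  d <- sim_logistic(200, 6, c(0.8, rep(0, 5)), seed = 42)
  df <- tibble::tibble(outcome = d$y, as.data.frame(d$x))
  r1 <- cv_evaluate(df, "lasso_GLM", reps = 12, folds = 3, seed = 5)
  r2 <- cv_evaluate(df, "lasso_GLM", reps = 24, folds = 3, seed = 5)
  ci_width <- r1$ci_upper - r1$ci_lower
  expect_lt(abs(r2$mean_auc - r1$mean_auc), ci_width / 2)
})

test_that("multiple-imputation pooling modes agree for m = 1 and both run for m > 1", {
  d <- sim_logistic(150, 5, c(1, rep(0, 4)), seed = 8)
  df <- tibble::tibble(outcome = d$y, as.data.frame(d$x))
  rp1 <- cv_evaluate(df, "lasso_GLM", reps = 3, folds = 3, seed = 2,
                     mi_combine = "pool")
  rr1 <- cv_evaluate(df, "lasso_GLM", reps = 3, folds = 3, seed = 2,
                     mi_combine = "rubin")
  expect_equal(rp1$replicates$auc, rr1$replicates$auc, tolerance = 1e-12)
  copies <- list(df, df, df)
  rr <- cv_evaluate(copies, "lasso_GLM", reps = 2, folds = 3, seed = 2,
                    mi_combine = "rubin")
  rp <- cv_evaluate(copies, "lasso_GLM", reps = 2, folds = 3, seed = 2,
                    mi_combine = "pool")
  # identical copies are refit with per-imputation seeds, so replicate AUCs
  # are close but need not be identical
  expect_lt(max(abs(rr$replicates$auc - rp$replicates$auc)), 0.05)
  expect_equal(rp$m, 3)
})

test_that("the leakage audit records training-only selection in every fold", {
  d <- sim_logistic(120, 5, c(1, rep(0, 4)), seed = 9)
  df <- tibble::tibble(outcome = d$y, as.data.frame(d$x))
  r <- cv_evaluate(df, "lasso_GLM", reps = 2, folds = 4, seed = 3)
  expect_equal(nrow(r$audit), 2 * 4)
  expect_true(all(r$audit$n_selection_rows < r$audit$n_total))
})

test_that("PEV equals an independent correlation recomputation and hits its anchors", {
  # a variable that is (almost) the outcome: PEV ~ 1
  y <- rep(c(0, 1), each = 40)
  d <- tibble::tibble(outcome = y,
                      base1 = withr::with_seed(2, rnorm(80)),
                      mirror = y + withr::with_seed(3, rnorm(80, 0, 0.01)))
  rep_ <- compute_pev(d, "mirror", base = "base1", seed = 1)
  expect_gt(rep_$pev[1], 0.95)
  # independent variables: null PEV bound
  d0 <- withr::with_seed(4, tibble::tibble(
    outcome = rbinom(1000, 1, 0.5), base1 = rnorm(1000), v = rnorm(1000)))
  rep0 <- compute_pev(d0, "v", base = "base1", seed = 2)
  expect_lt(abs(rep0$pev[1]), 0.07)
  # out-of-fold predictions stored on the report reproduce the correlation
  oof <- attr(rep0, "oof")
  manual_cor <- function(a, b) {
    mean((a - mean(a)) * (b - mean(b))) / (sd(a) * sd(b)) * length(a) / (length(a) - 1)
  }
  expect_equal(rep0$pev[1], manual_cor(d0$outcome, oof[, "v"]),
               tolerance = 1e-10)
  expect_equal(attr(rep0, "joint_pev"), manual_cor(d0$outcome, oof[, ".joint"]),
               tolerance = 1e-10)
})

test_that("PEV directions follow the multiple logistic regression signs", {
  d <- withr::with_seed(5, {
    up <- rnorm(400); down <- rnorm(400); b <- rnorm(400)
    tibble::tibble(outcome = rbinom(400, 1, plogis(1.2 * up - 1.2 * down)),
                   base1 = b, up = up, down = down)
  })
  rep_ <- compute_pev(d, c("up", "down"), base = "base1", seed = 3)
  expect_equal(rep_$direction[rep_$variable == "up"], "+")
  expect_equal(rep_$direction[rep_$variable == "down"], "-")
})

test_that("covariates-only analysis sets are platform-independent", {
  coh <- generate_cohort(tiny_cohort_config(seed = 15))
  pp <- preprocess_config(m = 2, mice_iterations = 2)
  a <- prepare_analysis_data(coh, "B", "lcms", "covariates_only", preprocess = pp)
  b <- prepare_analysis_data(coh, "B", "nmr", "covariates_only", preprocess = pp)
  expect_identical(a$datasets, b$datasets)
})

test_that("hormone-therapy exclusion removes exactly the flagged participants", {
  coh <- generate_cohort(tiny_cohort_config(seed = 16))
  pp <- preprocess_config(m = 2, mice_iterations = 2)
  aset <- suppressMessages(prepare_analysis_data(
    coh, "B", "lcms", "metabolites_base", preprocess = pp, exclude_ht = TRUE))
  expected <- sum(coh$participants$ht_current %in% c(0, NA) &
                    coh$participants$case_status %in% c("control", "case_B"))
  expect_equal(nrow(aset$datasets[[1]]), expected)
})

test_that("the study grid emits the full bookkeeping of reports", {
  coh <- generate_cohort(tiny_cohort_config(seed = 17))
  out <- suppressWarnings(suppressMessages(run_study(
    coh, reps = 2L, folds = 3L, seed = 4,
    procedures = standard_procedures()[c("lasso_GLM", "SL_GLM")],
    library = sl_lib_tiny(), v = 2L, k = 5L,
    preprocess = preprocess_config(m = 2, mice_iterations = 2),
    pooled = TRUE, run_selection = TRUE, run_pev = TRUE)))
  # 2 outcomes x (2 covariate-only + 2 platforms x 2 modes x 2 procedures)
  # + 2 pooled rows
  expect_equal(nrow(out$cv_auc), 2 * (2 + 2 * 2 * 2) + 2)
  expect_true(all(out$cv_auc$mean_auc >= 0 & out$cv_auc$mean_auc <= 1))
  expect_true(all(out$cv_auc$ci_lower <= out$cv_auc$mean_auc &
                    out$cv_auc$mean_auc <= out$cv_auc$ci_upper))
  pooled_rows <- out$cv_auc[out$cv_auc$platform %in% "pooled", ]
  expect_equal(unique(pooled_rows$procedure), "lasso_GLM")
  # selection tables: 2 outcomes x 2 platforms x 2 procedures
  expect_equal(nrow(out$selection), 8)
  expect_length(out$final_sets, 2)
})
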