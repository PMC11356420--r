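test_that("forced covariates are always selected by the lasso", {
  d <- sim_logistic(200, 10, rep(0, 10), seed = 1)
  res <- lasso_select(d$x, d$y, forced = c("v01", "v02"), seed = 1)
  expect_true(all(res$selected[res$variable %in% c("v01", "v02")]))
  expect_true(all(res$forced == (res$variable %in% c("v01", "v02"))))
  expect_true(all(res$variable %in% colnames(d$x)))
})

test_that("pure-noise metabolites are rarely selected alongside a strong forced covariate", {
  clean <- 0
  for (seed in 1:10) {
    d <- withr::with_seed(seed, {
      x <- matrix(rnorm(300 * 12), 300, 12,
                  dimnames = list(NULL, sprintf("v%02d", 1:12)))
      y <- rbinom(300, 1, plogis(1.5 * x[, 1]))
      list(x = x, y = y)
    })
    res <- lasso_select(d$x, d$y, forced = "v01", seed = seed)
    clean <- clean + (sum(res$selected) == 1)
  }
  expect_gte(clean, 8)
})

test_that("a 1-SD-effect metabolite is selected nearly always", {
  hits <- 0
  for (seed in 1:10) {
    d <- sim_logistic(1000, 10, c(0.5, rep(0, 8), 1), seed = 300 + seed)
    res <- lasso_select(d$x, d$y, forced = "v01", seed = seed)
    hits <- hits + res$selected[res$variable == "v10"]
  }
  expect_gte(hits, 9)
})

test_that("weighted ranks combine linearly and select the smallest k", {
  vims <- dplyr::bind_rows(
    tibble::tibble(learner = "l1", variable = c("a", "b", "c"),
                   importance = 0, rank = c(1L, 3L, 2L)),
    tibble::tibble(learner = "l2", variable = c("a", "b", "c"),
                   importance = 0, rank = c(5L, 2L, 1L)))
  res <- sl_rank_select(vims, weights = c(l1 = 0.7, l2 = 0.3), k = 1)
  # a: 0.7*1 + 0.3*5 = 2.2 beats b: 0.7*3 + 0.3*2 = 2.7
  expect_equal(res$statistic[res$variable == "a"], 2.2)
  expect_equal(res$statistic[res$variable == "b"], 2.7)
  expect_equal(res$variable[res$selected], "c")  # c: 0.7*2 + 0.3*1 = 1.7
  # degenerate weights reduce to a single learner's top-k
  res1 <- sl_rank_select(vims, weights = c(l1 = 1, l2 = 0), k = 2)
  expect_setequal(res1$variable[res1$selected], c("a", "c"))
})

test_that("weighted-rank selection equals a brute-force sort on random tables", {
  for (seed in 1:5) {
    p <- 30
    vims <- withr::with_seed(seed, dplyr::bind_rows(purrr::map(1:3, function(l) {
      tibble::tibble(learner = paste0("l", l),
                     variable = sprintf("m%02d", 1:p),
                     importance = 0,
                     rank = sample(p))
    })))
    w <- withr::with_seed(seed, {v <- runif(3); setNames(v / sum(v), paste0("l", 1:3))})
    res <- sl_rank_select(vims, weights = w, k = 7, forced = "m01")
    wr <- rowSums(vapply(1:3, function(l) {
      sub <- vims[vims$learner == paste0("l", l), ]
      w[l] * sub$rank[match(sprintf("m%02d", 1:p), sub$variable)]
    }, numeric(p)))
    oracle <- sprintf("m%02d", 1:p)[order(wr)]
    oracle <- union(setdiff(oracle, "m01")[1:7], "m01")
    expect_setequal(res$variable[res$selected], oracle)
    expect_lte(sum(res$selected), 7 + 1)
  }
})

test_that("k of at least p selects everything", {
  vims <- tibble::tibble(learner = "l1", variable = c("a", "b"),
                         importance = 0, rank = 1:2)
  res <- sl_rank_select(vims, weights = c(l1 = 1), k = 10)
  expect_true(all(res$selected))
})

test_that("stability selection applies the strict over-threshold rule", {
  make_results <- function(sel_counts, m = 10) {
    purrr::map(seq_len(m), function(i) {
      tibble::tibble(variable = names(sel_counts),
                     selected = i <= sel_counts,
                     statistic = 0, forced = FALSE)
    })
  }
  stab <- stability_select(make_results(c(keep = 8, drop = 7, never = 0)))
  expect_true(stab$final[stab$variable == "keep"])     # 0.8 > 0.7
  expect_false(stab$final[stab$variable == "drop"])    # 0.7 is not > 0.7
  expect_false(stab$final[stab$variable == "never"])
  # brute-force thresholding of a random indicator matrix
  m <- 12; p <- 40
  sel <- withr::with_seed(9, matrix(runif(p * m) < 0.5, p, m))
  results <- purrr::map(seq_len(m), function(i) {
    tibble::tibble(variable = sprintf("x%02d", 1:p), selected = sel[, i],
                   statistic = 0, forced = FALSE)
  })
  stab2 <- stability_select(results, threshold = 0.70)
  expect_equal(stab2$final, rowMeans(sel) > 0.70)
  expect_equal(stab2$frequency, rowMeans(sel))
  # raising the threshold never enlarges the final set
  finals <- vapply(c(0.5, 0.6, 0.7, 0.8, 0.9),
                   function(t) sum(stability_select(results, t)$final),
                   numeric(1))
  expect_true(all(diff(finals) <= 0))
})

test_that("stability selection rejects differing variable universes", {
  r1 <- tibble::tibble(variable = c("a", "b"), selected = TRUE,
                       statistic = 0, forced = FALSE)
  r2 <- tibble::tibble(variable = c("a", "c"), selected = TRUE,
                       statistic = 0, forced = FALSE)
  expect_error(stability_select(list(r1, r2)), "universes")
})

test_that("final unions follow the procedures-then-platforms rule", {
  same <- list(p1 = list(lasso = c("a", "b"), sl_rank = c("a", "b")))
  expect_setequal(union_final(same)$metabolites, c("a", "b"))
  disjoint <- list(p1 = list(lasso = c("a", "b", "c"),
                             sl_rank = c("d", "e", "f", "g")))
  expect_length(union_final(disjoint)$metabolites, 7)
  # 4 platforms x 2 procedures fixture vs hand-computed union
  sets <- list(
    lcms  = list(lasso = c("m1", "m2", "age"), sl_rank = c("m2", "m3")),
    lipid = list(lasso = character(),          sl_rank = c("m4", "age")),
    nmr   = list(lasso = c("m5", "bmi"),       sl_rank = c("m5")),
    gcms  = list(lasso = c("m6"),              sl_rank = c("m7", "bmi")))
  out <- union_final(sets, covariates = c("age", "bmi"))
  expect_setequal(out$metabolites, sprintf("m%d", 1:7))
  expect_setequal(out$covariates, c("age", "bmi"))
  expect_setequal(out$by_platform$lcms, c("m1", "m2", "m3", "age"))
})

test_that("signal features are selected more stably than null features", {
  # imputation-to-imputation variability comes from the lasso's internal CV
  d <- sim_logistic(600, 40, c(rep(0.4, 6), rep(0, 34)), seed = 77)
  results <- purrr::map(1:5, function(i) {
    lasso_select(d$x, d$y, seed = 1000 + i)
  })
  stab <- stability_select(results)
  sig <- stab$frequency[1:6]
  nul <- stab$frequency[7:40]
  expect_gt(median(sig), median(nul))
  pv <- stats::wilcox.test(sig, nul, alternative = "greater", exact = FALSE)$p.value
  expect_lt(pv, 0.01)
})
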