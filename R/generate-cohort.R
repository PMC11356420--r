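#' Generate a synthetic matched case-control cohort with metabolite platforms
#'
#' Produces a participant table (cases for two outcomes plus 1:1
#' optimally-matched controls), one feature table per metabolomics platform
#' with interspersed pooled QC rows, batch/run-order metadata and
#' below-detection-limit censoring, and a truth sidecar recording which
#' features carry signal. All randomness derives from `config$seed`; a fixed
#' seed reproduces the cohort exactly.
#'
#' Metabolite abundances are lognormal: a per-feature baseline, a
#' between-participant biological deviation, a within-batch drift curve
#' shared across features (scaled by a per-feature sensitivity), and
#' platform-specific technical noise. Signal features shift the case mean of
#' the configured outcome by `effect_size` total log-scale SDs, so the
#' single-feature oracle AUC is `pnorm(effect_size / sqrt(2))`. QC rows are
#' draws from the pooled baseline with technical noise and drift only.
#'
#' @param config A [cohort_config()].
#' @return An object of class `synthetic_cohort`: a list with `participants`
#'   (tibble), `features` (named list of tibbles with columns `sample_id`,
#'   `batch`, `run_order`, `is_qc`, then feature columns), `truth` (tibble of
#'   signal annotations), `pairing` (the matched pairs), and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  seeds <- derive_seeds(config$seed, 4 + length(config$platform_sizes))

  participants <- withr::with_seed(seeds[1], simulate_participants(config))
  pairing <- match_controls(participants, match_rule())
  keep <- c(participants$participant_id[participants$case_status != "control"],
            pairing$control_id)
  participants <- participants[participants$participant_id %in% keep, ]
  participants <- dplyr::left_join(
    participants,
    dplyr::select(pairing, participant_id = "case_id",
                  matched_control_id = "control_id"),
    by = "participant_id")
  participants <- withr::with_seed(
    seeds[2], simulate_risk_covariates(participants, config))
  participants <- withr::with_seed(
    seeds[3], inject_covariate_missingness(participants, config))

  truth <- withr::with_seed(seeds[4], draw_truth(config))
  platforms <- names(config$platform_sizes)
  features <- setNames(vector("list", length(platforms)), platforms)
  for (k in seq_along(platforms)) {
    features[[k]] <- withr::with_seed(
      seeds[4 + k],
      simulate_platform(platforms[k], participants, truth, config))
  }

  structure(list(participants = participants, features = features,
                 truth = truth, pairing = pairing, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>\n")
  tab <- table(x$participants$case_status)
  cat(sprintf("  participants: %d (%s)\n", nrow(x$participants),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  for (p in names(x$features)) {
    f <- x$features[[p]]
    nfeat <- sum(!names(f) %in% c("sample_id", "batch", "run_order", "is_qc"))
    cat(sprintf("  %s: %d features, %d rows (%d QC), %d batches\n",
                p, nfeat, nrow(f), sum(f$is_qc), max(f$batch)))
  }
  cat(sprintf("  signal features: %d (outcome A), %d (outcome B)\n",
              sum(x$truth$outcome == "A"), sum(x$truth$outcome == "B")))
  invisible(x)
}

# ---- participants -----------------------------------------------------------

race_levels <- c("white", "black", "hispanic", "other")

draw_base <- function(n) {
  visit <- sample(c(0, 12, 36, 72, 108), n, replace = TRUE,
                  prob = c(0.20, 0.38, 0.405, 0.01, 0.005))
  tibble::tibble(
    age = pmin(pmax(rnorm(n, 63, 7), 50), 79),
    enrollment_date = visit + runif(n, -1, 1),
    race_ethnicity = factor(
      sample(race_levels, n, replace = TRUE,
             prob = c(0.81, 0.12, 0.05, 0.02)),
      levels = race_levels)
  )
}

simulate_participants <- function(config) {
  n_cases <- config$n_cases_A + config$n_cases_B
  cases <- draw_base(n_cases)
  cases$case_status <- factor(
    c(rep("case_A", config$n_cases_A), rep("case_B", config$n_cases_B)),
    levels = c("control", "case_A", "case_B"))

  # Control pool: one guaranteed-compatible "twin" per case (same race, age
  # and enrollment inside the matching tolerances) so a feasible 1:1 matching
  # always exists, plus extra eligible controls drawn from the base
  # distribution.
  twins <- cases[, c("age", "enrollment_date", "race_ethnicity")]
  twins$age <- pmin(pmax(twins$age + runif(n_cases, -1.5, 1.5), 50), 79)
  twins$enrollment_date <- twins$enrollment_date + runif(n_cases, -1.5, 1.5)
  n_extra <- max(0L, ceiling(config$n_controls * config$control_pool_factor) -
                   n_cases)
  pool <- dplyr::bind_rows(twins, draw_base(n_extra))
  pool <- pool[sample(nrow(pool)), ]
  pool$case_status <- factor("control", levels = levels(cases$case_status))

  out <- dplyr::bind_rows(cases, pool)
  out$participant_id <- sprintf("P%05d", seq_len(nrow(out)))
  dplyr::select(out, "participant_id", "case_status", "age",
                "enrollment_date", "race_ethnicity")
}

# Risk covariates carry their own case-control association so that
# covariate-only prediction is informative (AUCs in the high 0.5s), with
# magnitudes in the order observed in large cohort summaries: adiposity and
# smoking higher in cases, screening history protective for the
# colorectal-like outcome, a risk-score analogue informative for the
# breast-like outcome.
simulate_risk_covariates <- function(participants, config) {
  n <- nrow(participants)
  st <- participants$case_status
  sh <- function(control, a, b) {
    ifelse(st == "case_A", a, ifelse(st == "case_B", b, control))
  }
  log_bmi <- rnorm(n, sh(log(27.2), log(27.2) + 0.05, log(27.2) + 0.06), 0.17)
  bmi <- exp(log_bmi)
  participants$bmi <- bmi
  participants$waist <- 2.2 * bmi + rnorm(n, sh(24, 25.5, 26), 6)
  drinker <- rbinom(n, 1, sh(0.55, 0.6, 0.55))
  participants$alcohol <- drinker * exp(rnorm(n, sh(-0.3, -0.1, -0.2), 0.9))
  participants$folate <- pmax(exp(rnorm(n, sh(log(590), log(625), log(615)), 0.42)), 40)
  participants$calcium <- pmax(rnorm(n, sh(1000, 1050, 1050), 420), 60)
  participants$red_meat <- exp(rnorm(n, sh(log(1.8), log(1.87), log(1.85)), 0.55))
  participants$energy_expend <- exp(rnorm(n, sh(log(7), log(7.1), log(7.2)), 1.05))
  participants$smoking <- rbinom(n, 1, sh(0.062, 0.078, 0.089))
  participants$colonoscopy <- rbinom(n, 1, sh(0.47, 0.44, 0.39))
  participants$polyp_removal <- rbinom(n, 1, sh(0.10, 0.07, 0.06))
  participants$gail_score <- exp(rnorm(n, sh(log(1.68), log(1.9), log(1.70)), 0.33))
  participants$ht_current <- rbinom(n, 1, sh(0.40, 0.37, 0.30))
  participants
}

inject_covariate_missingness <- function(participants, config) {
  for (v in names(config$covariate_missing_rates)) {
    if (!v %in% names(participants)) next
    rate <- config$covariate_missing_rates[[v]]
    if (rate <= 0) next
    miss <- runif(nrow(participants)) < rate
    participants[[v]][miss] <- NA
  }
  participants
}

# ---- matching ---------------------------------------------------------------

#' Optimally match controls to cases
#'
#' Pairs every case 1:1 with an eligible control of the same race/ethnicity,
#' within the rule's age and enrollment tolerances, minimising the total
#' tolerance-scaled distance (Jonker-Volgenant optimal assignment within each
#' race/ethnicity stratum). Errors name the stratum when too few eligible
#' controls exist, and list unmatched cases when the tolerances are
#' infeasible.
#'
#' @param participants A data frame with columns `participant_id`,
#'   `case_status` (`"control"` vs case levels), `age`, `enrollment_date`,
#'   `race_ethnicity`.
#' @param rule A [match_rule()].
#' @return A tibble of pairs: `case_id`, `control_id`, `age_gap`,
#'   `enrollment_gap`, `distance`, with attribute `total_distance`.
#' @export
match_controls <- function(participants, rule = match_rule()) {
  stopifnot(inherits(rule, "match_rule"))
  cases <- participants[participants$case_status != "control", ]
  controls <- participants[participants$case_status == "control", ]
  pairs <- list()
  for (stratum in unique(as.character(cases$race_ethnicity))) {
    ca <- cases[as.character(cases$race_ethnicity) == stratum, ]
    co <- controls[as.character(controls$race_ethnicity) == stratum, ]
    if (nrow(co) < nrow(ca)) {
      abort(sprintf(
        "matching infeasible in stratum '%s': %d cases but only %d eligible controls",
        stratum, nrow(ca), nrow(co)))
    }
    age_gap <- abs(outer(ca$age, co$age, "-"))
    enr_gap <- abs(outer(ca$enrollment_date, co$enrollment_date, "-"))
    cost <- age_gap / rule$age_tolerance + enr_gap / rule$enrollment_tolerance
    cost[age_gap > rule$age_tolerance | enr_gap > rule$enrollment_tolerance] <- Inf
    sol <- solve_assignment(cost)
    if (!sol$feasible) {
      abort(sprintf(
        "matching infeasible in stratum '%s': no tolerance-respecting control for case %s (and possibly others)",
        stratum, ca$participant_id[sol$failed_row]))
    }
    pairs[[stratum]] <- tibble::tibble(
      case_id = ca$participant_id,
      control_id = co$participant_id[sol$col4row],
      age_gap = age_gap[cbind(seq_len(nrow(ca)), sol$col4row)],
      enrollment_gap = enr_gap[cbind(seq_len(nrow(ca)), sol$col4row)],
      distance = cost[cbind(seq_len(nrow(ca)), sol$col4row)])
  }
  out <- dplyr::bind_rows(pairs)
  out <- out[order(match(out$case_id, cases$participant_id)), ]
  attr(out, "total_distance") <- sum(out$distance)
  out
}

#' Check a pairing against the matching rule, pair by pair
#'
#' Independent verification that every pair satisfies the rule: same
#' race/ethnicity, age gap within tolerance, enrollment gap within tolerance,
#' each control used at most once, and controls are actually controls.
#'
#' @inheritParams match_controls
#' @param pairing A tibble with columns `case_id` and `control_id`.
#' @return A logical vector, one entry per pair.
#' @export
check_pairing <- function(participants, pairing, rule = match_rule()) {
  idx <- function(id) match(id, participants$participant_id)
  ca <- idx(pairing$case_id)
  co <- idx(pairing$control_id)
  ok <- !is.na(ca) & !is.na(co) &
    participants$case_status[co] == "control" &
    participants$case_status[ca] != "control" &
    as.character(participants$race_ethnicity[ca]) ==
      as.character(participants$race_ethnicity[co]) &
    abs(participants$age[ca] - participants$age[co]) <= rule$age_tolerance &
    abs(participants$enrollment_date[ca] - participants$enrollment_date[co]) <=
      rule$enrollment_tolerance
  ok & !duplicated(pairing$control_id)
}

# ---- metabolite platforms ---------------------------------------------------

draw_truth <- function(config) {
  p <- config$platform_sizes[[config$signal_platform]]
  out <- list()
  for (oc in c("A", "B")) {
    k <- config$n_signal_features[[oc]]
    if (k == 0) next
    if (k > p) abort("more signal features requested than platform features")
    ids <- sort(sample.int(p, k))
    out[[oc]] <- tibble::tibble(
      platform = config$signal_platform,
      feature = feature_names(config$signal_platform, p)[ids],
      outcome = oc,
      effect = config$effect_size * rep_len(c(1, -1), k))
  }
  if (length(out) == 0) {
    return(tibble::tibble(platform = character(), feature = character(),
                          outcome = character(), effect = numeric()))
  }
  dplyr::bind_rows(out)
}

feature_names <- function(platform, p) sprintf("%s_%03d", platform, seq_len(p))

simulate_platform <- function(platform, participants, truth, config) {
  p <- config$platform_sizes[[platform]]
  feats <- feature_names(platform, p)
  n_study <- nrow(participants)
  study_order <- sample(n_study)

  # interleave QC rows: one after every qc_every study rows
  n_qc <- n_study %/% config$qc_every
  type <- rep("study", n_study + n_qc)
  if (n_qc > 0) {
    qc_pos <- seq_len(n_qc) * (config$qc_every + 1L)
    type[qc_pos] <- "qc"
  }
  n_tot <- length(type)
  sample_id <- character(n_tot)
  sample_id[type == "study"] <- participants$participant_id[study_order]
  sample_id[type == "qc"] <- sprintf("QC_%s_%03d", platform, seq_len(n_qc))

  n_batches <- config$n_batches %||% max(1L, ceiling(n_study / 27))
  batch <- rep(seq_len(n_batches), each = ceiling(n_tot / n_batches),
               length.out = n_tot)
  run_order <- seq_len(n_tot)

  mu <- rnorm(p, 11, 1.5)                       # feature log baselines
  sens <- runif(p, 0.5, 1.5)                    # drift sensitivity
  tech_sd <- config$tech_sd[[platform]]
  amp <- config$drift_amplitude[[platform]]
  total_sd <- sqrt(config$bio_sd^2 + tech_sd^2)

  # case shifts for signal features on this platform
  shift <- matrix(0, n_tot, p)
  tr <- truth[truth$platform == platform, ]
  if (nrow(tr) > 0) {
    status <- rep(NA_character_, n_tot)
    status[type == "study"] <-
      as.character(participants$case_status[study_order])
    for (i in seq_len(nrow(tr))) {
      j <- match(tr$feature[i], feats)
      affected <- !is.na(status) & status == paste0("case_", tr$outcome[i])
      shift[affected, j] <- shift[affected, j] + tr$effect[i] * total_sd
    }
  }

  # drift: a per-batch low-order polynomial in batch position u (0..1) on the
  # log scale, centred so drift leaves the batch mean unchanged, with random
  # per-batch sign and magnitude
  coefs <- matrix(sample(c(-1, 1), 2 * n_batches, replace = TRUE) *
                    runif(2 * n_batches, 0.5, 1), n_batches, 2)
  u <- stats::ave(run_order, batch, FUN = function(r) {
    if (length(r) == 1) 0.5 else (r - min(r)) / (max(r) - min(r))
  })
  drift <- if (config$drift_shape == "linear") {
    coefs[batch, 1] * amp * (u - 0.5)
  } else {
    coefs[batch, 1] * amp * (u - 0.5) + coefs[batch, 2] * amp * (u^2 - 1 / 3)
  }

  logx <- matrix(mu, n_tot, p, byrow = TRUE) + shift +
    drift %o% sens +
    matrix(rnorm(n_tot * p, 0, tech_sd), n_tot, p)
  is_study <- type == "study"
  logx[is_study, ] <- logx[is_study, ] +
    matrix(rnorm(sum(is_study) * p, 0, config$bio_sd), sum(is_study), p)
  x <- exp(logx)

  # below-LOD censoring: exactly the lowest floor(rate * n_study) study
  # values per feature are removed
  lod <- config$lod_missing_rate[[platform]]
  if (lod > 0) {
    n_cens <- floor(lod * sum(is_study))
    if (n_cens > 0) {
      study_idx <- which(is_study)
      for (j in seq_len(p)) {
        ord <- study_idx[order(x[study_idx, j])]
        x[ord[seq_len(n_cens)], j] <- NA
      }
    }
  }

  colnames(x) <- feats
  dplyr::bind_cols(
    tibble::tibble(sample_id = sample_id, batch = batch,
                   run_order = run_order, is_qc = type == "qc"),
    tibble::as_tibble(x))
}
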