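#' Assemble analysis-ready multiply imputed datasets for one analysis cell
#'
#' Applies the fixed preprocessing chain to the requested platform, imputes
#' the covariates by chained equations (ignoring the outcome), restricts to
#' the outcome-specific participants (all cases of that outcome plus all
#' controls - controls are reused for both outcomes), expands categorical
#' covariates to dummies, and returns `m` completed analysis tibbles with a
#' 0/1 `outcome` column.
#'
#' @param cohort A `synthetic_cohort` (or any list with `participants` and
#'   `features` of the same shape).
#' @param outcome `"A"` or `"B"`.
#' @param platform A platform name, `"pooled"` (all platforms joined after
#'   preprocessing), or `NULL` for a covariates-only dataset.
#' @param covariate_mode `"covariates_only"`, `"metabolites_base"`
#'   (metabolites plus the base design covariates), or `"metabolites_all"`
#'   (metabolites plus all risk-factor covariates).
#' @param preprocess A [preprocess_config()].
#' @param exclude_ht If `TRUE`, participants flagged as current hormone
#'   therapy users are removed before imputation (sensitivity analysis).
#' @param processed Optional named list of already-preprocessed feature
#'   tables (to avoid recomputation across calls).
#' @param imputations Optional precomputed [impute_covariates_mice()] result
#'   for the (possibly HT-filtered) participant table.
#' @return An `analysis_set`: list with `datasets` (list of `m` tibbles),
#'   `forced` (design covariate column names), `metabolites`, `covariates`,
#'   plus the cell labels.
#' @export
prepare_analysis_data <- function(cohort, outcome = c("A", "B"),
                                  platform = NULL,
                                  covariate_mode = c("metabolites_all",
                                                     "metabolites_base",
                                                     "covariates_only"),
                                  preprocess = preprocess_config(),
                                  exclude_ht = FALSE,
                                  processed = NULL,
                                  imputations = NULL) {
  outcome <- match.arg(outcome)
  covariate_mode <- match.arg(covariate_mode)
  participants <- cohort$participants
  if (exclude_ht) {
    participants <- participants[!(participants$ht_current %in% 1), ]
  }
  if (is.null(imputations)) {
    imputations <- impute_covariates_mice(
      participants, m = preprocess$m, seed = preprocess$imputation_seed,
      iterations = preprocess$mice_iterations)
  }

  risk_covs <- c("bmi", "waist", "alcohol", "folate", "calcium", "red_meat",
                 "energy_expend", "smoking", "colonoscopy", "polyp_removal",
                 "gail_score", "ht_current")
  risk_covs <- intersect(risk_covs, names(participants))

  met <- NULL
  if (!is.null(platform) && covariate_mode != "covariates_only") {
    plats <- if (identical(platform, "pooled")) names(cohort$features) else platform
    tabs <- purrr::map(plats, function(p) {
      tab <- if (!is.null(processed) && p %in% names(processed)) processed[[p]]
             else preprocess_platform(cohort$features[[p]], p, preprocess)
      tab[!tab$is_qc, c("sample_id", feature_cols(tab))]
    })
    met <- purrr::reduce(tabs, function(a, b) dplyr::left_join(a, b, by = "sample_id"))
  }

  keep_status <- c("control", paste0("case_", outcome))
  datasets <- purrr::map(imputations$imputations, function(d) {
    d <- d[d$case_status %in% keep_status, ]
    y <- as.integer(d$case_status != "control")
    base <- expand_covariates(d[, c("age", "enrollment_date", "race_ethnicity")])
    covs <- switch(covariate_mode,
      covariates_only = dplyr::bind_cols(
        base, expand_covariates(d[, risk_covs, drop = FALSE])),
      metabolites_base = base,
      metabolites_all = dplyr::bind_cols(
        base, expand_covariates(d[, risk_covs, drop = FALSE])))
    # per-imputation outlier truncation of covariates (metabolites were
    # truncated platform-wise in preprocess_platform)
    covs <- truncate_outliers(covs, preprocess$iqr_multiplier)
    out <- dplyr::bind_cols(tibble::tibble(outcome = y), covs)
    if (!is.null(met)) {
      mm <- met[match(d$participant_id, met$sample_id), , drop = FALSE]
      out <- dplyr::bind_cols(out, mm[, setdiff(names(mm), "sample_id")])
    }
    out
  })
  base_names <- names(expand_covariates(
    participants[, c("age", "enrollment_date", "race_ethnicity")]))
  metab_names <- if (is.null(met)) character() else setdiff(names(met), "sample_id")
  structure(list(datasets = datasets,
                 forced = base_names,
                 metabolites = metab_names,
                 covariates = setdiff(names(datasets[[1]]),
                                      c("outcome", metab_names)),
                 outcome = outcome, platform = platform,
                 covariate_mode = covariate_mode,
                 exclude_ht = exclude_ht),
            class = "analysis_set")
}

#' Run the full study grid on a cohort
#'
#' Orchestrates the complete analysis: preprocessing, covariate multiple
#' imputation, Monte-Carlo cross-validated AUC for every requested outcome x
#' platform x covariate-mode x procedure cell (plus covariates-only reference
#' reports per outcome), full-data stability selection per platform and
#' procedure, the union of final selections across procedures and platforms,
#' and per-variable PEV reports. Optional switches reproduce the sensitivity
#' analyses: `exclude_ht` removes current hormone-therapy users before
#' imputation; `pooled = TRUE` adds a pooled-platform analysis evaluated with
#' the lasso + GLM procedure only.
#'
#' @param cohort A `synthetic_cohort`.
#' @param outcomes Outcomes to analyse (default both).
#' @param platforms Platforms to analyse (default all in the cohort).
#' @param covariate_modes Metabolite covariate modes (default both).
#' @param procedures Named list of [procedure_spec()]s (default all six).
#' @param reps,folds Monte-Carlo replications and folds per replication.
#' @param seed Master seed.
#' @param library,v,k Super Learner library, internal folds, and rank-
#'   selection budget.
#' @param preprocess A [preprocess_config()].
#' @param exclude_ht,pooled Sensitivity switches.
#' @param stability_threshold Stability selection threshold (strict).
#' @param run_selection,run_pev Toggle the full-data selection and PEV
#'   stages.
#' @return A `study_report`: list with tibbles `cv_auc` (one row per report,
#'   full `cv_auc_report` in a list-column), `selection`, `final_sets`,
#'   `pev`, and the call settings.
#' @export
run_study <- function(cohort,
                      outcomes = c("A", "B"),
                      platforms = names(cohort$features),
                      covariate_modes = c("metabolites_base", "metabolites_all"),
                      procedures = standard_procedures(),
                      reps = 100L, folds = 5L, seed = 1L,
                      library = default_sl_library(), v = 10L, k = 20L,
                      preprocess = preprocess_config(),
                      exclude_ht = FALSE, pooled = FALSE,
                      stability_threshold = 0.70,
                      run_selection = TRUE, run_pev = TRUE) {
  participants <- cohort$participants
  if (exclude_ht) participants <- participants[!(participants$ht_current %in% 1), ]
  imputations <- impute_covariates_mice(
    participants, m = preprocess$m, seed = preprocess$imputation_seed,
    iterations = preprocess$mice_iterations)
  processed <- purrr::imap(cohort$features[platforms],
                           ~preprocess_platform(.x, .y, preprocess))

  prep <- function(oc, platform, mode) {
    prepare_analysis_data(
      list(participants = participants, features = cohort$features),
      outcome = oc, platform = platform, covariate_mode = mode,
      preprocess = preprocess, exclude_ht = FALSE,
      processed = processed, imputations = imputations)
  }
  eval_cell <- function(aset, proc, cell_seed) {
    cv_evaluate(aset$datasets, procedures[[proc]], outcome = "outcome",
                forced = aset$forced, reps = reps, folds = folds,
                seed = cell_seed, library = library, v = v, k = k)
  }

  cells <- list()
  seeds_pool <- derive_seeds(seed, 4096)
  next_seed <- local({i <- 0L; function() {i <<- i + 1L; seeds_pool[i]}})

  for (oc in outcomes) {
    aset <- prep(oc, NULL, "covariates_only")
    for (proc in names(procedures)) {
      rep_ <- eval_cell(aset, proc, next_seed())
      cells[[length(cells) + 1]] <- tibble::tibble(
        outcome = oc, platform = NA_character_,
        covariate_mode = "covariates_only", procedure = proc,
        mean_auc = rep_$mean_auc, ci_lower = rep_$ci_lower,
        ci_upper = rep_$ci_upper, report = list(rep_))
    }
    for (pf in platforms) {
      for (mode in covariate_modes) {
        aset <- prep(oc, pf, mode)
        for (proc in names(procedures)) {
          rep_ <- eval_cell(aset, proc, next_seed())
          cells[[length(cells) + 1]] <- tibble::tibble(
            outcome = oc, platform = pf, covariate_mode = mode,
            procedure = proc, mean_auc = rep_$mean_auc,
            ci_lower = rep_$ci_lower, ci_upper = rep_$ci_upper,
            report = list(rep_))
        }
      }
    }
    if (pooled) {
      aset <- prep(oc, "pooled", "metabolites_all")
      rep_ <- cv_evaluate(aset$datasets, procedure_spec("lasso_GLM"),
                          outcome = "outcome", forced = aset$forced,
                          reps = reps, folds = folds, seed = next_seed())
      cells[[length(cells) + 1]] <- tibble::tibble(
        outcome = oc, platform = "pooled", covariate_mode = "metabolites_all",
        procedure = "lasso_GLM", mean_auc = rep_$mean_auc,
        ci_lower = rep_$ci_lower, ci_upper = rep_$ci_upper,
        report = list(rep_))
    }
  }
  cv_auc <- dplyr::bind_rows(cells)

  selection <- NULL
  final_sets <- NULL
  pev <- NULL
  if (run_selection) {
    sel_rows <- list()
    final_by_outcome <- list()
    pev_rows <- list()
    for (oc in outcomes) {
      sets <- list()
      for (pf in platforms) {
        aset <- prep(oc, pf, "metabolites_all")
        lasso_res <- purrr::imap(aset$datasets, function(d, i) {
          lasso_select(d[, setdiff(names(d), "outcome")], d$outcome,
                       forced = aset$forced, seed = next_seed())
        })
        sl_res <- purrr::imap(aset$datasets, function(d, i) {
          slf <- fit_super_learner(d[, setdiff(names(d), "outcome")],
                                   d$outcome, library = library, v = v,
                                   seed = next_seed(), forced = aset$forced)
          sl_rank_select(compute_vims(slf), k = k, forced = aset$forced)
        })
        stab <- list(lasso = stability_select(lasso_res, stability_threshold),
                     sl_rank = stability_select(sl_res, stability_threshold))
        sets[[pf]] <- stab
        for (proc in names(stab)) {
          sel_rows[[length(sel_rows) + 1]] <- tibble::tibble(
            outcome = oc, platform = pf, procedure = proc,
            stability = list(stab[[proc]]))
        }
      }
      aset_any <- prep(oc, platforms[1], "metabolites_all")
      fins <- union_final(sets, covariates = aset_any$covariates)
      final_by_outcome[[oc]] <- fins
      if (run_pev) {
        sel_vars <- setdiff(c(fins$metabolites, fins$covariates),
                            aset_any$forced)
        if (length(sel_vars) > 0) {
          aset_all <- prep(oc, if (length(platforms) > 1) "pooled" else platforms,
                           "metabolites_all")
          d1 <- aset_all$datasets[[1]]
          sel_vars <- intersect(sel_vars, names(d1))
          pev_rep <- compute_pev(d1, sel_vars, outcome = "outcome",
                                 base = aset_all$forced, folds = folds,
                                 seed = next_seed())
          pev_rows[[length(pev_rows) + 1]] <- tibble::tibble(
            outcome = oc, joint_pev = attr(pev_rep, "joint_pev"),
            report = list(pev_rep))
        }
      }
    }
    selection <- dplyr::bind_rows(sel_rows)
    final_sets <- final_by_outcome
    if (length(pev_rows)) pev <- dplyr::bind_rows(pev_rows)
  }

  structure(list(cv_auc = cv_auc, selection = selection,
                 final_sets = final_sets, pev = pev,
                 settings = list(outcomes = outcomes, platforms = platforms,
                                 covariate_modes = covariate_modes,
                                 procedures = names(procedures),
                                 reps = reps, folds = folds, seed = seed,
                                 exclude_ht = exclude_ht, pooled = pooled,
                                 stability_threshold = stability_threshold)),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d CV-AUC reports (%s)\n", nrow(x$cv_auc),
              paste(x$settings$outcomes, collapse = "/")))
  print(dplyr::select(x$cv_auc, -"report"), n = 20)
  invisible(x)
}
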