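#' The six joint selection-plus-prediction procedures
#'
#' `procedure_spec()` builds one procedure; `standard_procedures()` returns
#' the full set of six evaluated throughout: the Super Learner on all
#' variables (`SL`), the Super Learner with a screen-augmented library
#' (`SL_screens`), and the four selector/predictor combinations
#' `lasso_GLM`, `lasso_SL`, `SL_GLM`, `SL_SL` (selection by lasso or by
#' Super-Learner-weighted ranks, prediction by logistic regression or by the
#' Super Learner).
#'
#' @param name One of `"SL"`, `"SL_screens"`, `"lasso_GLM"`, `"lasso_SL"`,
#'   `"SL_GLM"`, `"SL_SL"`.
#' @return A `procedure_spec` with fields `name`, `selector` (`"none"`,
#'   `"lasso"`, `"sl_rank"`), `predictor` (`"glm"`, `"super_learner"`),
#'   `screens` (flag, only valid without a selector).
#' @export
procedure_spec <- function(name = c("SL", "SL_screens", "lasso_GLM",
                                    "lasso_SL", "SL_GLM", "SL_SL")) {
  name <- match.arg(name)
  spec <- switch(name,
    SL         = list(selector = "none",    predictor = "super_learner", screens = FALSE),
    SL_screens = list(selector = "none",    predictor = "super_learner", screens = TRUE),
    lasso_GLM  = list(selector = "lasso",   predictor = "glm",           screens = FALSE),
    lasso_SL   = list(selector = "lasso",   predictor = "super_learner", screens = FALSE),
    SL_GLM     = list(selector = "sl_rank", predictor = "glm",           screens = FALSE),
    SL_SL      = list(selector = "sl_rank", predictor = "super_learner", screens = FALSE))
  structure(c(list(name = name), spec), class = "procedure_spec")
}

#' @rdname procedure_spec
#' @export
standard_procedures <- function() {
  nms <- c("SL", "SL_screens", "lasso_GLM", "lasso_SL", "SL_GLM", "SL_SL")
  setNames(purrr::map(nms, procedure_spec), nms)
}

#' Rank-based area under the ROC curve
#'
#' Mann-Whitney AUC with ties counted one half. Requires both classes.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (0/1).
#' @return The AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  check_outcome(labels)
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Fit the predictor half of a procedure on training data, return a
# prediction closure. The GLM path falls back to a lightly penalised ridge
# fit when the logistic regression separates.
fit_predictor <- function(predictor, x, y, library, v, seed, forced,
                          screens = FALSE) {
  if (predictor == "glm") {
    df <- data.frame(.y = y, x, check.names = FALSE)
    fit <- withr::with_seed(seed, suppressWarnings(
      glm(.y ~ ., data = df, family = binomial())))
    separated <- any(fitted(fit) > 1 - 1e-10) || any(fitted(fit) < 1e-10) ||
      anyNA(coef(fit))
    if (separated && ncol(x) >= 1) {
      xr <- if (ncol(x) < 2) cbind(x, .pad = 0) else x
      rfit <- glmnet::glmnet(xr, y, family = "binomial", alpha = 0,
                             lambda = 1e-3)
      return(function(newx) {
        newx <- newx[, colnames(x), drop = FALSE]
        if (ncol(x) < 2) newx <- cbind(newx, .pad = 0)
        as.vector(predict(rfit, newx = newx, type = "response"))
      })
    }
    function(newx) {
      as.vector(predict(fit, newdata = as.data.frame(newx), type = "response"))
    }
  } else {
    slf <- fit_super_learner(x, y, library = library, v = v, seed = seed,
                             forced = forced)
    function(newx) predict(slf, newx[, colnames(x), drop = FALSE])
  }
}

# Run a procedure's selector on training data only; returns the selected
# column names (always a superset of `forced`).
run_selector <- function(spec, x, y, forced, library, v, k, seed) {
  switch(spec$selector,
    none = colnames(x),
    lasso = {
      res <- lasso_select(x, y, forced = forced, seed = seed)
      res$variable[res$selected]
    },
    sl_rank = {
      slf <- fit_super_learner(x, y, library = library, v = v, seed = seed,
                               forced = forced)
      res <- sl_rank_select(compute_vims(slf), k = k, forced = forced)
      res$variable[res$selected]
    })
}

#' Monte-Carlo cross-validated AUC of a selection-plus-prediction procedure
#'
#' The honest-performance contract: in every replication a fresh stratified
#' partition is drawn, and within each training fold the procedure's variable
#' selection and prediction algorithm are refit from scratch - held-out rows
#' never inform selection. A replication's AUC is the mean of its fold AUCs.
#' With multiply imputed data, per-imputation held-out predictions are
#' averaged within each fold before the AUC (`mi_combine = "pool"`), or fold
#' AUCs are averaged across imputations (`"rubin"`).
#'
#' The report's 95% confidence interval is the normal approximation from the
#' standard error of the replication AUCs.
#'
#' @param data An `imputation_set`, a list of completed data frames, or a
#'   single data frame. Every column except `outcome` is a predictor.
#' @param spec A [procedure_spec()] (or its name).
#' @param outcome Name of the binary outcome column (default `"outcome"`).
#' @param forced Column names of the design covariates forced into every
#'   selection and model.
#' @param reps Number of Monte-Carlo replications (default 100).
#' @param folds Folds per replication (default 5, stratified).
#' @param seed Integer seed for all partitions and refits.
#' @param library Super Learner library for SL-based selectors/predictors.
#' @param v Internal Super Learner folds (default 10).
#' @param k Selection budget for the weighted-rank selector (default 20).
#' @param mi_combine `"pool"` (average predictions across imputations, then
#'   AUC) or `"rubin"` (average per-imputation AUCs).
#' @param null_calibrate If `TRUE`, the outcome labels are randomly permuted
#'   afresh in every replication - a null-calibration mode whose replication
#'   AUCs have mean exactly one half when the pipeline leaks no information
#'   from held-out rows.
#' @return A `cv_auc_report`: list with `replicates` (tibble of per-rep
#'   AUCs), `mean_auc`, `se`, `ci_lower`, `ci_upper`, and bookkeeping
#'   (procedure, n, folds, reps, seed, and a leakage audit of
#'   train/test-row counts).
#' @export
cv_evaluate <- function(data, spec, outcome = "outcome",
                        forced = character(), reps = 100L, folds = 5L,
                        seed = 1L, library = default_sl_library(), v = 10L,
                        k = 20L, mi_combine = c("pool", "rubin"),
                        null_calibrate = FALSE) {
  mi_combine <- match.arg(mi_combine)
  if (is.character(spec)) spec <- procedure_spec(spec)
  stopifnot(inherits(spec, "procedure_spec"))
  if (spec$screens && spec$selector != "none")
    abort("screens are only valid without a selector")

  datasets <- if (inherits(data, "imputation_set")) data$imputations
              else if (is.data.frame(data)) list(data)
              else data
  m <- length(datasets)
  y <- datasets[[1]][[outcome]]
  check_outcome(y)
  xs <- purrr::map(datasets, function(d) {
    as_numeric_matrix(tibble::as_tibble(d), drop = outcome)
  })
  bad <- setdiff(forced, colnames(xs[[1]]))
  if (length(bad)) abort(sprintf("forced columns not in data: %s",
                                 paste(bad, collapse = ", ")))
  if (spec$screens) library <- augment_with_screens(library)

  n <- length(y)
  rep_seeds <- derive_seeds(seed, reps)
  audit <- integer(0)
  rep_auc <- numeric(reps)
  for (r in seq_len(reps)) {
    sub_seeds <- derive_seeds(rep_seeds[r], 2 + 2 * folds * m)
    yr <- if (null_calibrate) {
      withr::with_seed(sub_seeds[1], sample(y))
    } else y
    fold_id <- draw_partition(yr, folds, sub_seeds[2])
    fold_aucs <- numeric(folds)
    for (fd in seq_len(folds)) {
      tr <- which(fold_id != fd)
      te <- which(fold_id == fd)
      stopifnot(length(intersect(tr, te)) == 0)   # leakage audit
      audit <- c(audit, length(tr))
      pred_m <- matrix(NA_real_, length(te), m)
      for (im in seq_len(m)) {
        s_sel <- sub_seeds[2 + (fd - 1) * m + im]
        s_fit <- sub_seeds[2 + folds * m + (fd - 1) * m + im]
        xtr <- xs[[im]][tr, , drop = FALSE]
        vars <- run_selector(spec, xtr, yr[tr], forced, library, v, k, s_sel)
        predictor_fun <- fit_predictor(
          spec$predictor, xtr[, vars, drop = FALSE], yr[tr],
          library = library, v = v, seed = s_fit, forced = forced,
          screens = spec$screens)
        pred_m[, im] <- predictor_fun(xs[[im]][te, vars, drop = FALSE])
      }
      fold_aucs[fd] <- if (mi_combine == "pool") {
        auc(rowMeans(pred_m), yr[te])
      } else {
        mean(apply(pred_m, 2, auc, labels = yr[te]))
      }
    }
    rep_auc[r] <- mean(fold_aucs)
  }

  se <- sd(rep_auc) / sqrt(reps)
  structure(list(
    replicates = tibble::tibble(rep = seq_len(reps), auc = rep_auc),
    mean_auc = mean(rep_auc), se = se,
    ci_lower = mean(rep_auc) - qnorm(0.975) * se,
    ci_upper = mean(rep_auc) + qnorm(0.975) * se,
    procedure = spec$name, n = n, m = m, folds = folds, reps = reps,
    seed = seed, mi_combine = mi_combine, null_calibrate = null_calibrate,
    audit = tibble::tibble(n_selection_rows = audit,
                           n_total = n)),
    class = "cv_auc_report")
}

# augment a base library with screened copies of one learner per kind,
# inheriting that kind's first tuning-parameter set
augment_with_screens <- function(library) {
  kinds <- vapply(library, `[[`, character(1), "kind")
  reps <- library[!duplicated(kinds)]
  screened <- purrr::flatten(purrr::map(reps, function(l) {
    list(learner(l$kind, params = l$params, screen = screen_top_univariate()),
         learner(l$kind, params = l$params, screen = screen_lasso()))
  }))
  sl_library(c(unclass(library), screened))
}

# stratified partition; redrawn (up to 25 tries) if any fold lacks a class
draw_partition <- function(y, folds, seed) {
  for (try in seq_len(25)) {
    id <- make_folds(y, folds, seed = (seed + try - 2) %% 2147483646 + 1)
    ok <- all(vapply(seq_len(folds),
                     function(f) length(unique(y[id == f])) == 2, logical(1)))
    if (ok) return(id)
  }
  abort("could not draw a partition with both classes in every fold")
}

#' @export
print.cv_auc_report <- function(x, ...) {
  cat(sprintf("<cv_auc_report> %s: mean CV-AUC %.3f (95%% CI %.3f-%.3f; %d reps x %d folds, n = %d%s)\n",
              x$procedure, x$mean_auc, x$ci_lower, x$ci_upper, x$reps,
              x$folds, x$n,
              if (x$null_calibrate) ", null-calibrated" else ""))
  invisible(x)
}

#' @rdname tidy.sl_fit
#' @method tidy cv_auc_report
#' @export
tidy.cv_auc_report <- function(x, ...) x$replicates

#' @rdname tidy.sl_fit
#' @method glance cv_auc_report
#' @export
glance.cv_auc_report <- function(x, ...) {
  tibble::tibble(procedure = x$procedure, mean_auc = x$mean_auc, se = x$se,
                 ci_lower = x$ci_lower, ci_upper = x$ci_upper,
                 reps = x$reps, folds = x$folds, n = x$n, m = x$m)
}

#' Proportion of explained variation of selected variables
#'
#' For each selected variable, fits a cross-validated logistic regression on
#' the design covariates plus that variable and correlates the out-of-fold
#' predictions with the observed binary outcome (the PEV, on the correlation
#' scale); the joint PEV uses all selected variables together. Directions
#' come from the coefficient signs of the full multiple logistic regression.
#'
#' @param data A completed (no missing values) data frame containing the
#'   outcome, the design covariates and the selected variables.
#' @param variables Character vector of selected (non-design) variables.
#' @param outcome Name of the binary outcome column.
#' @param base Character vector of design covariate columns included in every
#'   fit.
#' @param folds Cross-validation folds (default 5).
#' @param seed Partition seed.
#' @return A `pev_report`: tibble with columns `variable`, `pev`,
#'   `direction`; attributes `joint_pev` and `base`.
#' @export
compute_pev <- function(data, variables, outcome = "outcome",
                        base = character(), folds = 5L, seed = 1L) {
  if (length(variables) == 0) abort("no variables to evaluate")
  y <- data[[outcome]]
  check_outcome(y)
  x_all <- as_numeric_matrix(tibble::as_tibble(data), drop = outcome)
  fold_id <- draw_partition(y, folds, seed)

  oof <- function(cols) {
    p <- numeric(length(y))
    for (fd in seq_len(folds)) {
      tr <- fold_id != fd
      fun <- fit_predictor("glm", x_all[tr, cols, drop = FALSE], y[tr],
                           library = NULL, v = NULL, seed = seed,
                           forced = character())
      p[!tr] <- fun(x_all[!tr, cols, drop = FALSE])
    }
    p
  }
  oof_mat <- vapply(variables, function(v) oof(c(base, v)),
                    numeric(length(y)))
  oof_mat <- cbind(oof_mat, .joint = oof(c(base, variables)))
  pev <- vapply(variables, function(v) stats::cor(y, oof_mat[, v]),
                numeric(1))
  joint <- stats::cor(y, oof_mat[, ".joint"])

  full <- suppressWarnings(glm(
    y ~ ., data = data.frame(y = y, x_all[, c(base, variables), drop = FALSE],
                             check.names = FALSE),
    family = binomial()))
  cf <- coef(full)[variables]
  direction <- ifelse(is.na(cf) | cf == 0, "0", ifelse(cf > 0, "+", "-"))

  out <- tibble::tibble(variable = variables, pev = unname(pev),
                        direction = unname(direction))
  structure(out, joint_pev = joint, base = base, oof = oof_mat,
            class = c("pev_report", class(out)))
}
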