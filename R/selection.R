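#' Lasso variable selection with forced design covariates
#'
#' Fits a penalised logistic regression path with penalty factor zero for the
#' forced columns (so the design covariates are always retained with
#' unpenalised coefficients), selects lambda by 10-fold cross-validated
#' deviance, and returns every variable with a nonzero coefficient at the
#' chosen lambda, plus the forced set.
#'
#' @param x Numeric predictor matrix or all-numeric data frame.
#' @param y Binary outcome (0/1).
#' @param forced Column names forced into the model (penalty factor 0).
#' @param seed Seed for the cross-validation folds.
#' @param lambda_rule `"1se"` (default) for the one-standard-error rule,
#'   `"min"` for the deviance-minimising lambda. The conservative rule is the
#'   default because the deviance minimiser routinely drags marginal noise
#'   features into the support, defeating the clean-support behaviour a
#'   selection procedure is used for.
#' @param nfolds Cross-validation folds for lambda (default 10).
#' @return A `selection_result`: tibble with columns `variable`, `selected`,
#'   `statistic` (the coefficient at the chosen lambda), `forced`; attributes
#'   `procedure = "lasso"` and `lambda`.
#' @export
lasso_select <- function(x, y, forced = character(), seed = 1L,
                         lambda_rule = c("1se", "min"), nfolds = 10L) {
  lambda_rule <- match.arg(lambda_rule)
  x <- as_numeric_matrix(tibble::as_tibble(x))
  check_outcome(y)
  bad <- setdiff(forced, colnames(x))
  if (length(bad)) abort(sprintf("forced columns not in x: %s",
                                 paste(bad, collapse = ", ")))
  pf <- ifelse(colnames(x) %in% forced, 0, 1)
  # the path floor stops at 1% of lambda_max: the cross-validated choice sits
  # far above it, and the near-saturated tail is where coordinate descent
  # converges slowest
  fit <- withr::with_seed(seed,
    glmnet::cv.glmnet(x, y, family = "binomial", penalty.factor = pf,
                      nfolds = nfolds, type.measure = "deviance",
                      lambda.min.ratio = 0.01))
  s <- if (lambda_rule == "1se") fit$lambda.1se else fit$lambda.min
  cf <- coef(fit, s = s)
  beta <- setNames(as.vector(cf)[-1], rownames(cf)[-1])[colnames(x)]
  out <- tibble::tibble(
    variable = colnames(x),
    selected = beta != 0 | colnames(x) %in% forced,
    statistic = unname(beta),
    forced = colnames(x) %in% forced)
  structure(out, procedure = "lasso", lambda = s,
            class = c("selection_result", class(out)))
}

#' Select variables by Super-Learner-weighted importance ranks
#'
#' Combines per-learner importance ranks linearly with the ensemble's convex
#' weights - the weighted rank of variable j is `sum_l w_l * rank_l(j)` - and
#' selects the `k` variables with smallest weighted rank. Forced variables do
#' not consume the `k` budget: they are appended if not already selected.
#' Ties in the weighted rank are broken by stable column order.
#'
#' @param vims A `vim_table` from [compute_vims()].
#' @param weights Simplex weight vector named by learner; defaults to the
#'   weights stored on `vims`.
#' @param k Number of variables to select (default 20); `k >= p` selects all.
#' @param forced Variables always selected, outside the `k` budget.
#' @return A `selection_result` tibble with columns `variable`, `selected`,
#'   `statistic` (the weighted rank), `forced`; attribute
#'   `procedure = "sl_rank"`.
#' @export
sl_rank_select <- function(vims, weights = attr(vims, "weights"), k = 20,
                           forced = character()) {
  stopifnot(is.data.frame(vims),
            all(c("learner", "variable", "rank") %in% names(vims)))
  weights <- weights[weights > 0]
  use <- vims[vims$learner %in% names(weights), ]
  if (nrow(use) == 0) abort("no learner in vims carries positive weight")
  vars <- unique(vims$variable)
  wr <- setNames(rep(0, length(vars)), vars)
  for (l in names(weights)) {
    sub <- use[use$learner == l, ]
    wr[sub$variable] <- wr[sub$variable] + weights[[l]] * sub$rank
  }
  candidates <- setdiff(vars, forced)
  ord <- candidates[order(wr[candidates])]   # order() is stable: column-order ties
  top <- ord[seq_len(min(k, length(ord)))]
  out <- tibble::tibble(
    variable = vars,
    selected = vars %in% c(top, forced),
    statistic = unname(wr[vars]),
    forced = vars %in% forced)
  structure(out, procedure = "sl_rank",
            class = c("selection_result", class(out)))
}

#' Stability selection across multiply imputed datasets
#'
#' Given one `selection_result` per imputed dataset (same variable universe),
#' computes each variable's selection frequency and flags as final the
#' variables selected in strictly more than `threshold` of the imputations.
#'
#' @param results List of `selection_result` tibbles, one per imputation.
#' @param threshold Strict frequency threshold (default 0.70: "over 70%").
#' @return A `stability_table`: tibble with columns `variable`, `n_selected`,
#'   `frequency`, `forced`, `final`.
#' @export
stability_select <- function(results, threshold = 0.70) {
  stopifnot(length(results) >= 1)
  universes <- purrr::map(results, ~.x$variable)
  if (!all(purrr::map_lgl(universes, ~identical(.x, universes[[1]]))))
    abort("selection results have differing variable universes")
  sel <- vapply(results, function(r) r$selected, logical(nrow(results[[1]])))
  if (!is.matrix(sel)) sel <- matrix(sel, nrow = 1)
  freq <- rowMeans(sel)
  out <- tibble::tibble(
    variable = universes[[1]],
    n_selected = as.integer(rowSums(sel)),
    frequency = freq,
    forced = results[[1]]$forced,
    final = freq > threshold)
  structure(out, threshold = threshold, m = length(results),
            class = c("stability_table", class(out)))
}

#' Union of final selections across procedures and platforms
#'
#' Implements the final aggregation rule: per platform, the union of the
#' final sets from the two selection procedures; then, across platforms, the
#' union of the platform-specific metabolite sets, with covariates reported
#' as the unique covariates selected in any platform analysis.
#'
#' @param sets Nested named list: `sets[[platform]][[procedure]]` is either a
#'   `stability_table` (its `final` variables are used) or a character vector.
#' @param covariates Character vector of covariate names, used to split the
#'   overall union into metabolites versus covariates.
#' @return A list with `by_platform` (per-platform union over procedures),
#'   `metabolites` (union over platforms), and `covariates`.
#' @export
union_final <- function(sets, covariates = character()) {
  finals <- purrr::map(sets, function(platform_sets) {
    per_proc <- purrr::map(platform_sets, function(s) {
      if (is.data.frame(s)) s$variable[s$final] else as.character(s)
    })
    purrr::reduce(per_proc, union, .init = character())
  })
  overall <- purrr::reduce(finals, union, .init = character())
  list(by_platform = finals,
       metabolites = setdiff(overall, covariates),
       covariates = intersect(overall, covariates))
}
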