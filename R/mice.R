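#' Multiple imputation of covariates by chained equations, ignoring the outcome
#'
#' Produces `m` completed copies of the covariate table using iterated
#' per-variable conditional models: predictive mean matching for continuous
#' variables and Bayesian-draw logistic regression for binary variables.
#' The case/control label never enters any conditional model matrix, so
#' imputations are identical whatever the outcome column contains - a
#' requirement for honest downstream cross-validated performance assessment.
#'
#' Each chain starts from random draws of observed values and runs
#' `iterations` burn-in sweeps over the incomplete variables (ordered by
#' missingness). Parameter draws use the standard normal approximation to the
#' posterior (with a chi-square draw for the residual variance in the linear
#' case); predictive mean matching samples one of the `donors` observed
#' values with closest fitted mean.
#'
#' @param data A data frame of covariates, possibly with missing values.
#'   Columns listed in `exclude` (plus any non-covariate identifiers) are
#'   carried through untouched and never used as predictors.
#' @param m Number of imputed datasets (default 10).
#' @param seed Integer seed; chain `i` uses a seed derived from it.
#' @param iterations Burn-in sweeps per chain (default 10).
#' @param exclude Columns to exclude from every conditional model (the
#'   outcome and design identifiers). Defaults cover the cohort table's
#'   outcome and id columns.
#' @param donors Number of predictive-mean-matching donors (default 5).
#' @return An object of class `imputation_set`: list with `imputations` (list
#'   of `m` completed tibbles), `where` (logical matrix of imputed cells),
#'   `m`, `seed`, `iterations`.
#' @export
impute_covariates_mice <- function(data, m = 10L, seed = 1L,
                                   iterations = 10L,
                                   exclude = c("case_status", "outcome",
                                               "participant_id",
                                               "matched_control_id"),
                                   donors = 5L) {
  data <- tibble::as_tibble(data)
  carried <- intersect(exclude, names(data))
  covs <- setdiff(names(data), carried)
  sub <- data[, covs, drop = FALSE]
  where <- vapply(sub, is.na, logical(nrow(sub)))
  if (!is.matrix(where)) where <- matrix(where, nrow = nrow(sub),
                                         dimnames = list(NULL, covs))
  incomplete <- covs[colSums(where) > 0]
  high <- incomplete[colMeans(where[, incomplete, drop = FALSE]) > 0.5]
  if (length(high))
    warn(sprintf("variable(s) with >50%% missing: %s",
                 paste(high, collapse = ", ")))
  incomplete <- incomplete[order(colSums(where[, incomplete, drop = FALSE]))]

  if (length(incomplete) == 0) {
    imputations <- purrr::map(seq_len(m), ~data)
  } else {
    seeds <- derive_seeds(seed, m)
    imputations <- purrr::map(seq_len(m), function(i) {
      filled <- withr::with_seed(
        seeds[i],
        run_chain(sub, incomplete, where, iterations, donors))
      out <- data
      out[, covs] <- filled
      out
    })
  }
  structure(list(imputations = imputations, where = where, m = as.integer(m),
                 seed = as.integer(seed), iterations = as.integer(iterations)),
            class = "imputation_set")
}

#' @export
print.imputation_set <- function(x, ...) {
  cat(sprintf("<imputation_set> m = %d completed datasets, %d cells imputed across %d variables\n",
              x$m, sum(x$where), sum(colSums(x$where) > 0)))
  invisible(x)
}

run_chain <- function(sub, incomplete, where, iterations, donors) {
  # initial fill: random draws from each variable's observed values
  for (v in incomplete) {
    miss <- where[, v]
    sub[[v]][miss] <- sample(sub[[v]][!miss], sum(miss), replace = TRUE)
  }
  for (it in seq_len(iterations)) {
    for (v in incomplete) {
      miss <- where[, v]
      x <- expand_covariates(sub[, setdiff(names(sub), v), drop = FALSE])
      x <- as.matrix(x)
      keep <- apply(x, 2, function(col) stats::var(col) > 0)
      x <- cbind(`(Intercept)` = 1, x[, keep, drop = FALSE])
      y <- sub[[v]]
      binary <- length(unique(y[!miss])) == 2 && all(y[!miss] %in% c(0, 1))
      sub[[v]][miss] <- if (binary) {
        draw_logreg(x, y, miss)
      } else {
        draw_pmm(x, y, miss, donors)
      }
    }
  }
  sub
}

# Bayesian linear regression + predictive mean matching (type-1 matching:
# fitted means for donors, drawn means for recipients).
draw_pmm <- function(x, y, miss, donors) {
  xo <- x[!miss, , drop = FALSE]
  yo <- y[!miss]
  xtx <- crossprod(xo)
  ridge <- diag(ncol(xo)) * (1e-8 * mean(diag(xtx)) + 1e-12)
  xtx_inv <- solve(xtx + ridge)
  beta_hat <- xtx_inv %*% crossprod(xo, yo)
  resid <- yo - drop(xo %*% beta_hat)
  df <- max(length(yo) - ncol(xo), 1)
  sigma2_star <- sum(resid^2) / rchisq(1, df)
  cov_chol <- chol((xtx_inv + t(xtx_inv)) / 2)
  beta_star <- beta_hat + sqrt(sigma2_star) * t(cov_chol) %*% rnorm(ncol(xo))
  yhat_obs <- drop(xo %*% beta_hat)
  yhat_mis <- drop(x[miss, , drop = FALSE] %*% beta_star)
  vapply(yhat_mis, function(mu) {
    d <- abs(yhat_obs - mu)
    pick <- order(d)[seq_len(min(donors, length(d)))]
    yo[sample(pick, 1)]
  }, numeric(1))
}

draw_logreg <- function(x, y, miss) {
  xo <- x[!miss, , drop = FALSE]
  yo <- y[!miss]
  fit <- suppressWarnings(glm.fit(xo, yo, family = binomial()))
  beta_hat <- coef(fit)
  beta_hat[is.na(beta_hat)] <- 0
  w <- fit$weights
  info <- crossprod(xo * sqrt(pmax(w, 1e-8)))
  cov <- tryCatch(solve(info + diag(ncol(xo)) * 1e-8),
                  error = function(e) diag(ncol(xo)) * 0)
  beta_star <- beta_hat + drop(t(chol((cov + t(cov)) / 2)) %*% rnorm(ncol(xo)))
  p <- plogis(drop(x[miss, , drop = FALSE] %*% beta_star))
  rbinom(sum(miss), 1, p)
}
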