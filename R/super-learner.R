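#' Fit a Super Learner stacking ensemble for a binary outcome
#'
#' Fits every candidate learner of `library` in a V-fold cross-validation
#' (stratified by outcome), collects held-out probability predictions, and
#' finds the convex combination of learners minimising the cross-validated
#' negative log-likelihood (the non-negative log-likelihood loss). The
#' simplex-constrained minimisation uses a softmax reparameterisation with
#' BFGS from several starts (the uniform weight vector and each vertex);
#' held-out probabilities are clipped to `[eps, 1 - eps]` before the loss is
#' evaluated. Candidate learners are then refit on the full data for
#' prediction.
#'
#' A learner that fails in any fold is dropped with a warning and the
#' remaining weights renormalised.
#'
#' @param x Numeric matrix (or all-numeric data frame) of predictors.
#' @param y Binary outcome coded 0/1.
#' @param library An [sl_library()]; default [default_sl_library()].
#' @param v Number of cross-validation folds for weight estimation
#'   (default 10). `n` must be at least `10 * v`.
#' @param seed Integer seed controlling fold assignment and every learner's
#'   internal randomness.
#' @param forced Column names a screen must always keep.
#' @param eps Probability clipping bound (default 1e-6).
#' @return An object of class `sl_fit` with elements `weights` (simplex
#'   vector over learners), `cv_risk` (per-learner mean held-out negative
#'   log-likelihood), `cv_risk_ensemble`, `fits` (full-data fitted learners),
#'   `cv_predictions` (n x L matrix of held-out predictions), `folds`,
#'   `columns`, `seed`.
#' @export
fit_super_learner <- function(x, y, library = default_sl_library(), v = 10L,
                              seed = 1L, forced = character(), eps = 1e-6) {
  x <- as_numeric_matrix(tibble::as_tibble(x))
  check_outcome(y)
  stopifnot(nrow(x) == length(y))
  if (nrow(x) < 10 * v)
    abort(sprintf("need n >= 10 * v (= %d) observations for v = %d folds",
                  10 * v, v))
  if (!inherits(library, "sl_library")) library <- sl_library(library)
  L <- length(library)
  seeds <- derive_seeds(seed, v * L + L + 1)
  folds <- make_folds(y, v, seed = seeds[v * L + L + 1])

  z <- matrix(NA_real_, nrow(x), L, dimnames = list(NULL, names(library)))
  failed <- setNames(rep(FALSE, L), names(library))
  for (fold in seq_len(v)) {
    tr <- folds != fold
    for (l in seq_len(L)) {
      if (failed[l]) next
      sd_l <- seeds[(fold - 1) * L + l]
      res <- tryCatch(
        {
          fit <- fit_learner(library[[l]], x[tr, , drop = FALSE], y[tr],
                             seed = sd_l, forced = forced)
          predict_learner(fit, x[!tr, , drop = FALSE])
        },
        error = function(e) e)
      if (inherits(res, "error")) {
        warn(sprintf("learner '%s' failed in fold %d and was dropped: %s",
                     names(library)[l], fold, conditionMessage(res)))
        failed[l] <- TRUE
      } else {
        z[!tr, l] <- res
      }
    }
  }
  if (all(failed)) abort("every learner failed during cross-validation")
  keep <- which(!failed)
  zk <- z[, keep, drop = FALSE]

  weights_k <- optimize_simplex_weights(zk, y, eps = eps)
  cv_risk_k <- apply(zk, 2, neg_log_lik, y = y, eps = eps)
  weights <- setNames(rep(0, L), names(library))
  cv_risk <- setNames(rep(NA_real_, L), names(library))
  weights[keep] <- weights_k
  cv_risk[keep] <- cv_risk_k

  fits <- vector("list", L)
  for (l in keep) {
    fits[[l]] <- fit_learner(library[[l]], x, y,
                             seed = seeds[v * L + l], forced = forced)
  }
  names(fits) <- names(library)

  structure(list(
    library = library, weights = weights, cv_risk = cv_risk,
    cv_risk_ensemble = neg_log_lik(drop(zk %*% weights_k), y, eps = eps),
    fits = fits, cv_predictions = z, folds = folds, dropped = names(failed)[failed],
    columns = colnames(x), n = nrow(x), v = v, seed = seed, eps = eps),
    class = "sl_fit")
}

# Minimise mean negative log-likelihood of Z %*% w over the probability
# simplex. Softmax reparameterisation keeps the problem smooth and
# unconstrained; multiple starts (uniform + each vertex) guard against local
# minima at the faces.
optimize_simplex_weights <- function(z, y, eps = 1e-6) {
  L <- ncol(z)
  if (L == 1) return(1)
  softmax <- function(a) {
    e <- exp(a - max(a))
    e / sum(e)
  }
  nll_w <- function(w) neg_log_lik(drop(z %*% w), y, eps = eps)
  obj <- function(a) nll_w(softmax(a))
  starts <- rbind(rep(0, L), 8 * diag(L))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    o <- tryCatch(optim(starts[i, ], obj, method = "BFGS",
                        control = list(maxit = 500)),
                  error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  w <- softmax(best$par)
  w[w < 1e-10] <- 0
  w <- w / sum(w)
  # exact vertices and the uniform vector compete as candidate solutions, so
  # the ensemble risk can never exceed the best single learner's risk
  candidates <- c(list(w, rep(1 / L, L)),
                  purrr::map(seq_len(L), ~as.numeric(seq_len(L) == .x)))
  vals <- vapply(candidates, nll_w, numeric(1))
  candidates[[which.min(vals)]]
}

#' Predict from a fitted Super Learner
#'
#' @param object An `sl_fit`.
#' @param new_data Matrix or data frame whose columns match the training
#'   columns; a mismatch is an error listing the missing and extra columns.
#' @param ... Unused.
#' @return A numeric vector of probabilities in `[0, 1]`.
#' @export
predict.sl_fit <- function(object, new_data, ...) {
  new_data <- as_numeric_matrix(tibble::as_tibble(new_data))
  missing <- setdiff(object$columns, colnames(new_data))
  extra <- setdiff(colnames(new_data), object$columns)
  if (length(missing) || length(extra)) {
    abort(sprintf("column mismatch; missing: [%s]; extra: [%s]",
                  paste(missing, collapse = ", "),
                  paste(extra, collapse = ", ")))
  }
  new_data <- new_data[, object$columns, drop = FALSE]
  p <- rep(0, nrow(new_data))
  for (l in seq_along(object$fits)) {
    w <- object$weights[l]
    if (w == 0 || is.null(object$fits[[l]])) next
    p <- p + w * predict_learner(object$fits[[l]], new_data)
  }
  pmin(pmax(p, 0), 1)
}

#' Variable importance table of a fitted Super Learner
#'
#' Per learner, importances are the absolute standardised coefficients
#' (elastic net) or impurity/gain decreases (forests, boosted trees),
#' converted to ranks with 1 = most important; ties are broken by column
#' order so ranks are a permutation of `1..p` within each learner.
#'
#' @param fit An `sl_fit`.
#' @return A `vim_table`: tibble with columns `learner`, `variable`,
#'   `importance`, `rank`, carrying the ensemble `weights` as an attribute.
#' @export
compute_vims <- function(fit) {
  stopifnot(inherits(fit, "sl_fit"))
  rows <- purrr::imap(fit$fits, function(fl, nm) {
    if (is.null(fl)) return(NULL)
    imp <- learner_importance(fl, fit$columns)
    tibble::tibble(learner = nm, variable = names(imp),
                   importance = unname(imp),
                   rank = unname(rank(-imp, ties.method = "first")))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "weights") <- fit$weights
  class(out) <- c("vim_table", class(out))
  out
}

#' @export
print.sl_fit <- function(x, ...) {
  cat(sprintf("<sl_fit> n = %d, %d learners, V = %d\n", x$n,
              length(x$library), x$v))
  tab <- tibble::tibble(learner = names(x$weights),
                        weight = round(unname(x$weights), 4),
                        cv_risk = round(unname(x$cv_risk), 4))
  print(tab, n = Inf)
  cat(sprintf("ensemble CV risk: %.4f\n", x$cv_risk_ensemble))
  invisible(x)
}

#' Tidy and glance methods for Super Learner fits
#'
#' `tidy()` returns one row per candidate learner with its ensemble weight
#' and cross-validated risk; `glance()` returns a one-row model summary.
#'
#' @param x,... An `sl_fit` and unused arguments.
#' @return A tibble.
#' @method tidy sl_fit
#' @export
tidy.sl_fit <- function(x, ...) {
  tibble::tibble(learner = names(x$weights),
                 kind = vapply(x$library, `[[`, character(1), "kind"),
                 weight = unname(x$weights),
                 cv_risk = unname(x$cv_risk),
                 dropped = names(x$weights) %in% x$dropped)
}

#' @rdname tidy.sl_fit
#' @method glance sl_fit
#' @export
glance.sl_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_learners = length(x$library),
                 n_dropped = length(x$dropped), v = x$v,
                 cv_risk_ensemble = x$cv_risk_ensemble,
                 cv_risk_best_single = min(x$cv_risk, na.rm = TRUE))
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance
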