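#' @importFrom rlang %||% abort warn inform
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   across bind_rows bind_cols left_join pull n all_of any_of row_number
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_dbl map_int map_lgl map2 imap pmap keep discard
#' @importFrom stats quantile median sd var rnorm runif rbinom loess predict
#'   glm binomial coef lm qnorm plogis qlogis optim rchisq model.matrix
#'   complete.cases setNames
#' @importFrom utils head tail
NULL

# Derive child RNG seeds from a parent seed without touching the global
# stream outside withr::with_seed. Values stay below 2^31 - 1.
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Stratified fold assignment: within each outcome class, shuffled indices are
# dealt out cyclically so every fold sees both classes whenever counts allow.
make_folds <- function(y, v, seed = NULL) {
  stopifnot(v >= 2, length(y) >= v)
  assign_one <- function(idx) {
    idx <- sample(idx)
    setNames(rep_len(sample(seq_len(v)), length(idx)), idx)
  }
  draw <- function() {
    folds <- integer(length(y))
    for (cl in unique(y)) {
      idx <- which(y == cl)
      a <- assign_one(idx)
      folds[as.integer(names(a))] <- unname(a)
    }
    folds
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

clip_prob <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

neg_log_lik <- function(p, y, eps = 1e-6) {
  p <- clip_prob(p, eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Expand a covariate data frame to an all-numeric design
#'
#' Factor and character columns are converted to treatment-contrast dummy
#' columns (first level as reference); logical columns become 0/1. Numeric
#' columns pass through unchanged. Column order is preserved, with dummies
#' replacing their parent factor in place.
#'
#' @param data A data frame of covariates (no outcome column required).
#' @return A tibble with only numeric columns.
#' @export
expand_covariates <- function(data) {
  cols <- purrr::imap(data, function(col, nm) {
    if (is.numeric(col)) {
      out <- tibble::tibble(!!nm := as.numeric(col))
    } else if (is.logical(col)) {
      out <- tibble::tibble(!!nm := as.numeric(col))
    } else {
      f <- factor(col)
      if (nlevels(f) < 2) {
        out <- tibble::tibble(!!nm := rep(0, length(f)))
      } else {
        mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
        colnames(mm) <- paste0(nm, "_", make.names(levels(f)[-1]))
        out <- tibble::as_tibble(mm)
      }
    }
    out
  })
  dplyr::bind_cols(cols)
}

as_numeric_matrix <- function(data, drop = character()) {
  data <- data[, setdiff(names(data), drop), drop = FALSE]
  stopifnot(all(vapply(data, is.numeric, logical(1))))
  as.matrix(data)
}

is_binary01 <- function(y) {
  is.numeric(y) && all(y %in% c(0, 1))
}

check_outcome <- function(y) {
  if (!is_binary01(y)) abort("outcome must be coded 0/1")
  if (length(unique(y)) < 2) abort("outcome is degenerate: only one class present")
  invisible(y)
}
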