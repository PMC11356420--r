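#' Define a candidate learner for the Super Learner library
#'
#' Three learner kinds are supported, mirroring a standard binary-outcome
#' stacking library: penalised logistic regression (`"elastic_net"`, tuned
#' over lambda by internal cross-validation at a fixed mixing parameter),
#' gradient-boosted trees (`"boosted_trees"`), and probability random forests
#' (`"random_forest"`). Each distinct tuning-parameter combination is a
#' separate library member. A learner may carry a screen: a feature-selection
#' rule re-applied inside every training fold before the learner is fit.
#'
#' @param kind One of `"elastic_net"`, `"boosted_trees"`, `"random_forest"`.
#' @param name Unique name within a library; defaults to the kind plus key
#'   parameters.
#' @param params Named list of tuning parameters. Elastic net: `alpha`
#'   (mixing, default 1), `nfolds` (internal CV for lambda, default 5),
#'   `lambda_rule` (`"min"` or `"1se"`). Boosted trees: `max_depth` (2),
#'   `nrounds` (200), `eta` (0.1). Random forest: `num_trees` (500),
#'   `min_node_size` (10).
#' @param screen `NULL`, or a screen created by [screen_top_univariate()] /
#'   [screen_lasso()].
#' @return An object of class `learner_spec`.
#' @export
learner <- function(kind = c("elastic_net", "boosted_trees", "random_forest"),
                    name = NULL, params = list(), screen = NULL) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    elastic_net = list(alpha = 1, nfolds = 5, lambda_rule = "min"),
    boosted_trees = list(max_depth = 2, nrounds = 200, eta = 0.1),
    random_forest = list(num_trees = 500, min_node_size = 10))
  params <- utils::modifyList(defaults, params)
  if (is.null(name)) {
    key <- switch(kind,
      elastic_net = sprintf("enet_a%s", params$alpha),
      boosted_trees = sprintf("xgb_d%s", params$max_depth),
      random_forest = sprintf("rf_t%s", params$num_trees))
    name <- if (is.null(screen)) key else paste0(key, "_", screen$label)
  }
  structure(list(name = name, kind = kind, params = params, screen = screen),
            class = "learner_spec")
}

#' Assemble a Super Learner library
#'
#' @param ... `learner_spec` objects.
#' @return A named list of learners (class `sl_library`); names must be
#'   unique.
#' @export
sl_library <- function(...) {
  learners <- list(...)
  if (length(learners) == 1 && is.list(learners[[1]]) &&
      !inherits(learners[[1]], "learner_spec")) {
    learners <- learners[[1]]
  }
  stopifnot(all(vapply(learners, inherits, logical(1), "learner_spec")))
  nms <- vapply(learners, `[[`, character(1), "name")
  if (anyDuplicated(nms)) abort("learner names must be unique within a library")
  structure(setNames(learners, nms), class = "sl_library")
}

#' Default candidate library
#'
#' Elastic net at mixing parameters 0.25, 0.5, 0.75 and 1; boosted trees at
#' depths 2 and 4 (500 rounds); and a 1000-tree random forest.
#'
#' @param screens If `TRUE`, each learner kind is additionally wrapped with a
#'   univariate top-k screen and a lasso-support screen, for the
#'   screen-augmented library variant.
#' @return An `sl_library`.
#' @export
default_sl_library <- function(screens = FALSE) {
  base <- c(
    purrr::map(c(0.25, 0.5, 0.75, 1),
               ~learner("elastic_net", params = list(alpha = .x))),
    purrr::map(c(2, 4),
               ~learner("boosted_trees",
                        params = list(max_depth = .x, nrounds = 500))),
    list(learner("random_forest", params = list(num_trees = 1000))))
  if (screens) {
    reps <- list(learner("elastic_net"),
                 learner("boosted_trees"),
                 learner("random_forest"))
    screened <- purrr::map(reps, function(l) {
      list(learner(l$kind, params = l$params, screen = screen_top_univariate()),
           learner(l$kind, params = l$params, screen = screen_lasso()))
    })
    base <- c(base, purrr::flatten(screened))
  }
  sl_library(base)
}

#' Feature screens for screen-augmented libraries
#'
#' `screen_top_univariate()` keeps the `k` features with largest absolute
#' two-sample t statistic between outcome classes; `screen_lasso()` keeps the
#' lasso support at the cross-validated lambda. Both always keep `forced`
#' columns. Screens are re-applied inside each training fold so held-out data
#' never inform the feature set.
#'
#' @param k Number of features kept by the univariate screen.
#' @return A screen object used in [learner()].
#' @export
screen_top_univariate <- function(k = 20) {
  structure(list(type = "top_univariate", k = k,
                 label = sprintf("top%d", k)), class = "sl_screen")
}

#' @rdname screen_top_univariate
#' @export
screen_lasso <- function() {
  structure(list(type = "lasso", label = "lassoscr"), class = "sl_screen")
}

apply_screen <- function(screen, x, y, forced = character(), seed = 1L) {
  feats <- setdiff(colnames(x), forced)
  kept <- switch(screen$type,
    top_univariate = {
      tstat <- vapply(feats, function(j) {
        a <- x[y == 1, j]; b <- x[y == 0, j]
        s <- sqrt(var(a) / length(a) + var(b) / length(b))
        if (!is.finite(s) || s == 0) 0 else abs(mean(a) - mean(b)) / s
      }, numeric(1))
      feats[order(-tstat)[seq_len(min(screen$k, length(feats)))]]
    },
    lasso = {
      fit <- withr::with_seed(seed,
        glmnet::cv.glmnet(x, y, family = "binomial", nfolds = 5))
      cf <- coef(fit, s = "lambda.min")
      sel <- rownames(cf)[as.vector(cf != 0)]
      intersect(feats, sel)
    },
    abort(sprintf("unknown screen type '%s'", screen$type)))
  union(forced, kept)
}

# ---- fit / predict / importance per learner kind ---------------------------

fit_learner <- function(spec, x, y, seed = 1L, forced = character()) {
  keep <- colnames(x)
  if (!is.null(spec$screen)) {
    keep <- apply_screen(spec$screen, x, y, forced = forced, seed = seed)
    keep <- intersect(colnames(x), keep)
    if (length(keep) == 0) keep <- colnames(x)
    x <- x[, keep, drop = FALSE]
  }
  model <- switch(spec$kind,
    elastic_net = fit_enet(spec, x, y, seed),
    boosted_trees = fit_xgb(spec, x, y, seed),
    random_forest = fit_rf(spec, x, y, seed))
  structure(list(spec = spec, model = model, keep = keep,
                 columns = colnames(x)),
            class = "fitted_learner")
}

predict_learner <- function(fit, x) {
  x <- x[, fit$keep, drop = FALSE]
  p <- switch(fit$spec$kind,
    elastic_net = {
      if (isTRUE(fit$model$padded)) x <- cbind(x, .pad = 0)
      as.vector(predict(fit$model$fit, newx = x,
                        s = fit$model$s, type = "response"))
    },
    boosted_trees = predict(fit$model, xgboost::xgb.DMatrix(x, nthread = 1)),
    random_forest = predict(fit$model, data = x,
                            num.threads = 1)$predictions[, "1"])
  clip_prob(as.numeric(p), 0)
}

# Variable importance on the learner's training columns: absolute
# standardised coefficient for the elastic net, impurity (Gini) decrease for
# forests, split gain for boosted trees. Screened-out columns get 0.
learner_importance <- function(fit, all_columns) {
  imp <- switch(fit$spec$kind,
    elastic_net = {
      cf <- coef(fit$model$fit, s = fit$model$s)
      v <- setNames(abs(as.vector(cf)[-1]), rownames(cf)[-1])
      v * fit$model$col_sd[names(v)]
    },
    boosted_trees = {
      tab <- xgboost::xgb.importance(model = fit$model)
      setNames(tab$Gain, tab$Feature)
    },
    random_forest = fit$model$variable.importance)
  out <- setNames(rep(0, length(all_columns)), all_columns)
  imp <- imp[names(imp) %in% all_columns]
  out[names(imp)] <- imp
  out
}

fit_enet <- function(spec, x, y, seed) {
  p <- spec$params
  padded <- ncol(x) < 2
  if (padded) {
    # cv.glmnet requires >= 2 columns; pad with a zero column
    x <- cbind(x, .pad = 0)
  }
  fit <- withr::with_seed(seed,
    glmnet::cv.glmnet(x, y, family = "binomial", alpha = p$alpha,
                      nfolds = p$nfolds, standardize = TRUE))
  s <- if (identical(p$lambda_rule, "1se")) fit$lambda.1se else fit$lambda.min
  list(fit = fit, s = s, padded = padded,
       col_sd = apply(x, 2, sd))
}

fit_xgb <- function(spec, x, y, seed) {
  p <- spec$params
  withr::with_seed(seed,
    xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = p$max_depth,
                    eta = p$eta, nthread = 1),
      data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
      nrounds = p$nrounds, verbose = 0))
}

fit_rf <- function(spec, x, y, seed) {
  p <- spec$params
  ranger::ranger(x = x, y = factor(y, levels = c("0", "1")),
                 probability = TRUE, importance = "impurity",
                 num.trees = p$num_trees, min.node.size = p$min_node_size,
                 num.threads = 1, seed = seed)
}
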