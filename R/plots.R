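#' Plot mean CV-AUC with confidence intervals across procedures
#'
#' A point-range figure of the Monte-Carlo cross-validated AUC per procedure,
#' faceted by outcome, with shape and colour distinguishing the covariate
#' modes (covariates only, metabolites + base covariates, metabolites + all
#' covariates) - the standard way to display whether metabolites add
#' predictive value beyond the risk factors.
#'
#' @param cv_auc The `cv_auc` tibble of a [run_study()] report (columns
#'   `outcome`, `platform`, `covariate_mode`, `procedure`, `mean_auc`,
#'   `ci_lower`, `ci_upper`).
#' @return A ggplot object.
#' @export
plot_cv_auc <- function(cv_auc) {
  ggplot2::ggplot(cv_auc,
                  ggplot2::aes(x = .data$procedure, y = .data$mean_auc,
                               colour = .data$covariate_mode,
                               shape = .data$covariate_mode)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$ci_lower, ymax = .data$ci_upper),
      position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::facet_wrap(~.data$outcome, labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "CV-AUC (mean over replications, 95% CI)",
                  colour = "variables", shape = "variables") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot the distribution of replicate AUCs of one report
#'
#' @param object A `cv_auc_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cv_auc_report
#' @export
autoplot.cv_auc_report <- function(object, ...) {
  ggplot2::ggplot(object$replicates, ggplot2::aes(x = .data$auc)) +
    ggplot2::geom_histogram(bins = 20, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = object$mean_auc, linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = c(object$ci_lower, object$ci_upper),
                        linetype = "dashed") +
    ggplot2::labs(x = "replicate CV-AUC", y = "count",
                  title = sprintf("%s: mean CV-AUC %.3f", object$procedure,
                                  object$mean_auc)) +
    ggplot2::theme_bw()
}

#' Plot stability-selection frequencies
#'
#' Selection frequency across imputations per variable, with the strict
#' stability threshold marked; final variables are highlighted.
#'
#' @param stability A `stability_table` from [stability_select()].
#' @param top Show only the `top` most frequently selected variables.
#' @return A ggplot object.
#' @export
plot_stability <- function(stability, top = 30) {
  thr <- attr(stability, "threshold")
  df <- dplyr::arrange(stability, dplyr::desc(.data$frequency))
  df <- utils::head(df, top)
  df$variable <- factor(df$variable, levels = rev(df$variable))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frequency, y = .data$variable,
                                   fill = .data$final)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = thr, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick",
                                          `FALSE` = "grey70")) +
    ggplot2::labs(x = "selection frequency across imputations", y = NULL,
                  fill = sprintf("> %.0f%%", 100 * thr)) +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot
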