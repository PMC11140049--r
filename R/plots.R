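#' Scatter plot of per-SNP effects with fitted method lines
#'
#' The conventional MR scatter display: outcome effects against exposure
#' effects (exposure orientation positive) with one line per estimator —
#' slope equal to the causal estimate and, for MR-Egger, its intercept.
#'
#' @param h Harmonized set.
#' @param estimates Estimate tibble (e.g. [mr_all()]).
#' @return A ggplot object.
#' @export
plot_mr_scatter <- function(h, estimates) {
  sc <- scatter_data(h, estimates)
  ggplot2::ggplot(sc$points, ggplot2::aes(x = .data$beta_exp, y = .data$beta_out)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$beta_out - .data$se_out,
                                        ymax = .data$beta_out + .data$se_out),
                           linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$beta_exp - .data$se_exp,
                                         xmax = .data$beta_exp + .data$se_exp),
                            linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::geom_abline(data = sc$lines,
                         ggplot2::aes(intercept = .data$intercept,
                                      slope = .data$slope,
                                      colour = .data$method)) +
    ggplot2::labs(x = "SNP effect on exposure", y = "SNP effect on outcome",
                  colour = "Method") +
    ggplot2::theme_minimal()
}

#' Funnel plot of per-SNP ratios against precision
#'
#' @param h Harmonized set.
#' @param ivw Optional IVW estimate row; drawn as the reference line.
#' @return A ggplot object.
#' @export
plot_mr_funnel <- function(h, ivw = NULL) {
  fd <- funnel_data(h)
  p <- ggplot2::ggplot(fd, ggplot2::aes(x = .data$ratio, y = .data$precision)) +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::labs(x = "Per-SNP causal estimate (Wald ratio)", y = "Precision (1/SE)") +
    ggplot2::theme_minimal()
  if (!is.null(ivw)) {
    p <- p + ggplot2::geom_vline(xintercept = ivw$beta, linetype = "dashed")
  }
  p
}

#' Leave-one-out forest plot
#'
#' @param loo An `"mr_loo"` tibble from [leave_one_out()].
#' @return A ggplot object.
#' @export
plot_mr_loo <- function(loo) {
  loo <- dplyr::mutate(loo, excluded = factor(.data$excluded,
                                              levels = rev(.data$excluded)))
  ggplot2::ggplot(loo, ggplot2::aes(x = .data$beta, y = .data$excluded)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "IVW estimate excluding the named SNP", y = NULL) +
    ggplot2::theme_minimal()
}

#' Forest plot of method estimates or meta-analyzed cohorts
#'
#' @param x An estimate tibble (rows with `method` or `study`, `or`,
#'   `or_ci_low`, `or_ci_high`) or an `"mr_meta_report"`.
#' @return A ggplot object on the odds-ratio scale.
#' @export
plot_mr_forest <- function(x) {
  if (inherits(x, "mr_meta_report")) x <- x$forest
  label_col <- if ("study" %in% names(x)) "study" else "method"
  x <- dplyr::mutate(x, .label = factor(.data[[label_col]],
                                        levels = rev(unique(.data[[label_col]]))))
  ggplot2::ggplot(x, ggplot2::aes(x = .data$or, y = .data$.label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dotted") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$or_ci_low,
                                         xmax = .data$or_ci_high), height = 0.2) +
    ggplot2::geom_point(shape = 15, size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Default display for an MR run report (scatter plot)
#'
#' @param object An `"mr_report"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mr_report
#' @export
autoplot.mr_report <- function(object, ...) {
  plot_mr_scatter(harmonized_effects(object$harmonized), object$estimates) +
    ggplot2::ggtitle(sprintf("%s → %s", object$exposure_name, object$outcome_name))
}
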