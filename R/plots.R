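# ggplot2 views of experiment results: relative bias and CV against the
# scenario axes, one panel per estimator, with the unbiased (bias = 1) and
# management-precision (CV = 20%) reference lines.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

summary_x_axis <- function(s) {
  if ("fecundity_mean" %in% names(s) && length(unique(s$fecundity_mean)) > 1) {
    "fecundity_mean"
  } else if ("fecundity_sd" %in% names(s) &&
             length(unique(s$fecundity_sd)) > 1) {
    "fecundity_sd"
  } else if ("fraction" %in% names(s) && length(unique(s$fraction)) > 1) {
    "fraction"
  } else if ("species" %in% names(s)) {
    "species"
  } else {
    "method"
  }
}

#' Plot mean relative bias per estimator
#'
#' Mean relative bias (N-hat / N) with +/- SD error bars against the most
#' informative scenario axis, faceted by method, with a dashed line at the
#' unbiased value of 1 and a grey band marking estimates within 20% of the
#' truth.
#'
#' @param summary A summary tibble from [summarize_bias()] or
#'   [tidy()][tidy.kin_experiment] of a `kin_experiment`.
#' @return A ggplot object.
#' @export
plot_bias <- function(summary) {
  xvar <- summary_x_axis(summary)
  aes_args <- ggplot2::aes(x = .data[[xvar]], y = .data$mean_bias)
  gg <- ggplot2::ggplot(summary, aes_args) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf, ymin = 0.8, ymax = 1.2,
                      alpha = 0.15) +
    ggplot2::geom_hline(yintercept = 1, linetype = "longdash")
  if ("fraction" %in% names(summary) && xvar != "fraction" &&
      length(unique(summary$fraction)) > 1) {
    gg <- gg + ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean_bias - .data$sd_bias,
                   ymax = .data$mean_bias + .data$sd_bias,
                   colour = factor(.data$fraction)),
      position = ggplot2::position_dodge(width = 0.5)) +
      ggplot2::labs(colour = "sampling\nintensity")
  } else {
    gg <- gg + ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean_bias - .data$sd_bias,
                   ymax = .data$mean_bias + .data$sd_bias))
  }
  gg + ggplot2::facet_wrap(~method) +
    ggplot2::labs(y = "relative bias (estimate / truth)", x = xvar)
}

#' Plot the coefficient of variation per estimator
#'
#' Mean per-population CV (%) of the relative bias, faceted by method, with
#' the 20% management-utility threshold marked.
#'
#' @param summary A summary tibble from [summarize_bias()].
#' @return A ggplot object.
#' @export
plot_cv <- function(summary) {
  xvar <- summary_x_axis(summary)
  gg <- ggplot2::ggplot(summary,
                        ggplot2::aes(x = .data[[xvar]], y = .data$cv_pct)) +
    ggplot2::geom_hline(yintercept = 20, linetype = "longdash")
  if ("fraction" %in% names(summary) && xvar != "fraction" &&
      length(unique(summary$fraction)) > 1) {
    gg <- gg + ggplot2::geom_point(
      ggplot2::aes(colour = factor(.data$fraction))) +
      ggplot2::labs(colour = "sampling\nintensity")
  } else {
    gg <- gg + ggplot2::geom_point()
  }
  gg + ggplot2::facet_wrap(~method) +
    ggplot2::labs(y = "CV of relative bias (%)", x = xvar)
}

#' Autoplot method for experiments
#'
#' @param object A `kin_experiment`.
#' @param type `"bias"` or `"cv"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kin_experiment
#' @export
autoplot.kin_experiment <- function(object, type = c("bias", "cv"), ...) {
  type <- match.arg(type)
  if (type == "bias") plot_bias(object$summary) else plot_cv(object$summary)
}
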