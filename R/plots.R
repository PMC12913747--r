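# Optional ggplot2 figures for PSA output.

utils::globalVariables(c("wtp", "probability", "delta_effect", "delta_cost"))

#' Plot a cost-effectiveness acceptability curve
#'
#' @param curve A `ceac_curve` from [ceac()].
#' @param thresholds WTP values to mark with vertical reference lines.
#' @return A ggplot object.
#' @export
plot_ceac <- function(curve, thresholds = c(10000, 50000)) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_ceac requires the 'ggplot2' package")
  }
  ggplot2::ggplot(as.data.frame(curve),
                  ggplot2::aes(x = wtp, y = probability)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = thresholds, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (USD per QALY)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}

#' Plot PSA draws on the cost-effectiveness plane
#'
#' Incremental effect on the x-axis, incremental cost on the y-axis,
#' with the WTP ray through the origin.
#'
#' @param samples A `psa_samples` data frame.
#' @param wtp WTP threshold for the reference ray (USD/QALY).
#' @return A ggplot object.
#' @export
plot_icer_scatter <- function(samples, wtp = 50000) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_icer_scatter requires the 'ggplot2' package")
  }
  ggplot2::ggplot(as.data.frame(samples),
                  ggplot2::aes(x = delta_effect, y = delta_cost)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.6) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey40") +
    ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = "dashed",
                         colour = "firebrick") +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (USD)",
                  title = "ICER scatter on the cost-effectiveness plane",
                  subtitle = sprintf("dashed ray: $%s per QALY",
                                     format(wtp, big.mark = ","))) +
    ggplot2::theme_minimal()
}
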