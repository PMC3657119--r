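#' Plot class-level visual ranges
#'
#' Dot-and-errorbar plot of the posterior class means of the minimum and
#' maximum half-maximum wavelengths, one panel of points per class.
#'
#' @param range_summaries `range_summaries` table from [run_pipeline()].
#' @return A ggplot object.
#' @export
plot_visual_ranges <- function(range_summaries) {
  ggplot2::ggplot(range_summaries,
                  ggplot2::aes(x = .data$mean, y = .data$level_label,
                               colour = .data$quantity)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2) +
    ggplot2::labs(x = "wavelength (nm)", y = NULL,
                  colour = NULL,
                  title = "Class-level half-maximum sensitivity limits") +
    ggplot2::theme_minimal()
}

#' Plot percentage of the visual range stimulated per class and lamp
#'
#' @param percent_summaries `percent_summaries` table from [run_pipeline()].
#' @return A ggplot object.
#' @export
plot_percent_stimulated <- function(percent_summaries) {
  ggplot2::ggplot(percent_summaries,
                  ggplot2::aes(x = .data$level_label, y = .data$mean,
                               colour = .data$lamp_type)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5),
                        size = 2) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      position = ggplot2::position_dodge(width = 0.5), width = 0.2) +
    ggplot2::labs(x = NULL, y = "% of visual range stimulated",
                  colour = "lamp",
                  title = "Visual-range stimulation by lamp technology") +
    ggplot2::theme_minimal()
}
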