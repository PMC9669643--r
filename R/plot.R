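# Visual summary of a resolved plastome structure.

#' Plot a plastome structure
#'
#' Draws the four regions as segments on the linearized coordinate axis.
#' Requires ggplot2.
#'
#' @param structure A [plastome_structure()].
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_structure <- function(structure, title = "Plastome structure") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort("ggplot2 is required for plotting")
  }
  r <- structure$regions
  r$region <- factor(toupper(r$region), levels = c("LSC", "IRB", "SSC", "IRA"))
  ggplot2::ggplot(r) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start, xend = .data$end,
                                       y = .data$region, yend = .data$region,
                                       colour = .data$region),
                          linewidth = 6, show.legend = FALSE) +
    ggplot2::labs(x = "position (bp)", y = NULL, title = title) +
    ggplot2::theme_minimal()
}
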