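#' Four-quadrant better-worse scatter plot
#'
#' Plots each need at (|DSI|, SI) with the centroid as the quadrant origin
#' (|DSI| on the x-axis, SI on the y-axis). The first quadrant (high SI,
#' high |DSI|) holds one-dimensional needs, the second (high SI, low |DSI|)
#' attractive, the third indifferent, and the fourth (low SI, high |DSI|)
#' must-be needs.
#'
#' @param analysis A [kano_analysis()] result.
#' @param label Label points with their need ids (default `TRUE`).
#' @return A ggplot object.
#' @export
#' @examples
#' plot_quadrants(kano_analysis(ccec_counts()))
plot_quadrants <- function(analysis, label = TRUE) {
  co <- analysis$coefficients
  ranking <- analysis$ranking
  df <- data.frame(need_id = co$need_id,
                   si = co$si,
                   abs_dsi = abs(co$dsi),
                   attribute = ranking$attribute[match(co$need_id,
                                                       ranking$need_id)])
  cx <- analysis$centroid$mean_abs_dsi
  cy <- analysis$centroid$mean_si
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$abs_dsi, y = .data$si,
                                        colour = .data$attribute)) +
    ggplot2::geom_vline(xintercept = cx, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_hline(yintercept = cy, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_colour_manual(values = c(M = "#d62728", O = "#1f77b4",
                                            A = "#2ca02c", I = "#7f7f7f"),
                                 name = "Attribute") +
    ggplot2::labs(x = "Worse coefficient |DSI|", y = "Better coefficient SI",
                  title = "Kano quadrant classification",
                  subtitle = sprintf("centroid (|DSI|, SI) = (%.3f, %.3f)",
                                     cx, cy)) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::theme_minimal()
  if (label) {
    p <- p + ggplot2::geom_text(ggplot2::aes(label = .data$need_id),
                                vjust = -0.8, size = 3, show.legend = FALSE)
  }
  p
}
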