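#' Plot a colony snapshot
#'
#' Cells at a recorded step over the slime field (snapshot nearest in time),
#' freeloaders highlighted.
#'
#' @param object A `phototax_record`.
#' @param t Recorded step to draw (default: last).
#' @param slime Draw the slime raster underneath.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phototax_record <- function(object, t = max(object$times),
                                     slime = TRUE, ...) {
  pos <- positions_at(object, t)
  df <- tibble(x = pos[, 1], y = pos[, 2], freeloader = object$freeloader)
  p <- ggplot2::ggplot()
  if (slime) {
    sl <- tidy(slime_at_step(object, t))
    if (nrow(sl) > 0)
      p <- p + ggplot2::geom_raster(
        data = sl, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
        ggplot2::scale_fill_gradient(low = "white", high = "grey30",
                                     name = "slime")
  }
  p +
    ggplot2::geom_point(data = df,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$freeloader),
                        size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "forestgreen",
                                            `TRUE` = "red"),
                                 guide = if (any(df$freeloader)) "legend" else "none",
                                 name = "freeloader") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("t = %g", t), x = "x", y = "y") +
    ggplot2::theme_minimal()
}

#' Rose plot of movement directions
#'
#' @param object A [direction_histogram()].
#' @param ... Unused.
#' @return A ggplot object (polar coordinates).
#' @export
autoplot.direction_histogram <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$bin_mid * 180 / pi,
                               y = .data$count)) +
    ggplot2::geom_col(width = 360 / nrow(object), fill = "steelblue",
                      colour = "grey20", linewidth = 0.2) +
    ggplot2::coord_polar(theta = "x", start = -pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(0, 360),
                                breaks = seq(0, 315, by = 45)) +
    ggplot2::labs(x = NULL, y = "count") +
    ggplot2::theme_minimal()
}

#' Plot kymograph traces
#'
#' @param kymo Output of [kymograph()].
#' @param highlight How many randomly chosen cells to colour distinctly.
#' @param alpha Line transparency for the background traces.
#' @return A ggplot object.
#' @export
plot_kymograph <- function(kymo, highlight = 2, alpha = 0.2) {
  ids <- unique(kymo$cell_id)
  hl <- sample(ids, min(highlight, length(ids)))
  ggplot2::ggplot(kymo, ggplot2::aes(x = .data$step, y = .data$coord,
                                     group = .data$cell_id)) +
    ggplot2::geom_line(alpha = alpha, colour = "grey40") +
    ggplot2::geom_line(data = kymo[kymo$cell_id %in% hl, ],
                       ggplot2::aes(colour = factor(.data$cell_id)),
                       linewidth = 0.6) +
    ggplot2::scale_colour_brewer(palette = "Set1", name = "cell") +
    ggplot2::labs(x = "step", y = "coordinate") +
    ggplot2::theme_minimal()
}
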