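#' Plot a morphology as a 2D projection
#'
#' Draws each parent-child segment in the x-y plane, coloured by structure,
#' with line width proportional to local diameter.
#'
#' @param m a `morphology`.
#' @return a ggplot object.
#' @export
plot_morphology <- function(m) {
  stopifnot(inherits(m, "morphology"))
  p <- m$points
  seg <- p[p$parent_id != -1L, ]
  df <- tibble(x = p$x[seg$parent_id], y = p$y[seg$parent_id],
               xend = seg$x, yend = seg$y, structure = seg$structure,
               diameter = 2 * seg$radius)
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend,
                                       colour = .data$structure,
                                       linewidth = .data$diameter)) +
    ggplot2::scale_linewidth(range = c(0.2, 2), guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.comparison_graph <- function(object, ...) {
  d <- object$data |>
    group_by(.data$group, .data$bin, .data$bin_lo, .data$bin_hi) |>
    summarise(mean = mean(.data$value),
              sem = if (n() > 1) stats::sd(.data$value) / sqrt(n()) else 0,
              .groups = "drop") |>
    mutate(x = (.data$bin_lo + .data$bin_hi) / 2)
  xlab <- if (object$mode == "distance_dependence") {
    if (object$scale == "normalized") "path distance (% of max)" else "path distance (µm)"
  } else {
    if (object$scale == "normalized") sprintf("%s (%% of max)", object$descriptor)
    else object$descriptor
  }
  ylab <- if (object$mode == "distance_dependence") object$descriptor
  else "fraction of dendritic surface"
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$mean,
                                  colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sem,
                                          ymax = .data$mean + .data$sem),
                             size = 0.2) +
    ggplot2::labs(x = xlab, y = ylab, colour = NULL,
                  title = sprintf("%s arbor (%s scale)", object$arbor, object$scale)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.traces <- function(object, ...) {
  df <- as_tibble(object) |>
    tidyr::pivot_longer(-"time", names_to = "compartment", values_to = "v")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$v,
                                   colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "voltage deviation (mV)", colour = NULL) +
    ggplot2::theme_minimal()
}
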