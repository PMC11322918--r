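# ggplot2 visualizations for each result type.

#' @method autoplot flow_field
#' @export
autoplot.flow_field <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x * 1e3, .data$y * 1e3,
                                   fill = .data$speed * 1e6)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "speed (um/s)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = "Darcy speed in the tissue chamber")
}

#' @method autoplot concentration_field
#' @export
autoplot.concentration_field <- function(object, ...) {
  prof <- gradient_metrics(object)$profile
  ggplot2::ggplot(prof, ggplot2::aes(.data$y * 1e6, .data$concentration,
                                     colour = .data$time / 3600,
                                     group = .data$time)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_viridis_c(name = "time (h)") +
    ggplot2::labs(x = "cross-chamber position (um)",
                  y = "normalized concentration",
                  title = "Morphogen gradient formation")
}

#' @method autoplot frap_track
#' @export
autoplot.frap_track <- function(object, ...) {
  ok <- object[object$valid, ]
  ggplot2::ggplot(ok, ggplot2::aes(.data$x, .data$y, colour = .data$time)) +
    ggplot2::geom_path() +
    ggplot2::geom_point() +
    ggplot2::scale_colour_viridis_c(name = "time (s)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)",
                  title = "Bleached-spot centroid track")
}

#' @method autoplot orientation_sample
#' @export
autoplot.orientation_sample <- function(object, bin_width = 10, ...) {
  h <- angle_histogram(object, bin_width = bin_width)
  ggplot2::ggplot(h, ggplot2::aes(.data$bin_mid, .data$frequency)) +
    ggplot2::geom_col(width = bin_width * 0.9) +
    ggplot2::scale_x_continuous(breaks = seq(0, 180, 30), limits = c(0, 180)) +
    ggplot2::labs(x = "fiber angle (deg)", y = "weighted frequency",
                  title = "Fiber orientation distribution")
}

#' @method autoplot cyst_shape
#' @export
autoplot.cyst_shape <- function(object, protrusions = NULL, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_path() +
    ggplot2::annotate("point", x = object$centroid["x"],
                      y = object$centroid["y"], shape = 3) +
    ggplot2::geom_hline(yintercept = object$centroid["y"],
                        linetype = "dashed", colour = "grey50") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)", title = "Cyst contour")
  if (!is.null(protrusions) && nrow(protrusions) > 0) {
    p <- p + ggplot2::geom_point(
      data = protrusions,
      ggplot2::aes(.data$tip_x, .data$tip_y), colour = "red", size = 2
    )
  }
  p
}

#' @method autoplot curvature_profile
#' @export
autoplot.curvature_profile <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$arc_position, .data$curvature)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "arc position (um)", y = "curvature (1/um)",
                  title = "Contour curvature profile")
}
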