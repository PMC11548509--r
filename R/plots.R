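#' Plot a scan frame as world-frame points
#'
#' @param frame A scan frame (`sts_scan` or data frame with `alpha_deg`,
#'   `dist_mm`).
#' @param geom A [sensor_geometry()].
#' @return A ggplot.
#' @export
plot_scan <- function(frame, geom = attr(frame, "geom")) {
  cloud <- polar_to_points(frame, geom)
  ggplot2::ggplot(cloud, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = "Scan point cloud (sensor at x = 0)")
}

#' Plot a phase stream as a timeline
#'
#' @param phases Tibble from [run_spd()] or [run_pipeline()].
#' @return A ggplot.
#' @export
plot_phase_stream <- function(phases) {
  ggplot2::ggplot(phases,
                  ggplot2::aes(.data$t_s, y = 1, fill = .data$phase)) +
    ggplot2::geom_tile(height = 1) +
    ggplot2::scale_fill_brewer(palette = "Set2", drop = FALSE) +
    ggplot2::labs(x = "time (s)", y = NULL, fill = "phase") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' @export
autoplot.sts_lts_fit <- function(object, ...) {
  d <- object$data
  d$fitted <- predict(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$t_s)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$lts_mm), size = 0.8,
                        colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::labs(x = "time (s)", y = "lts (mm)",
                  title = sprintf("Gudermannian fit (%s branch): ki = %.2f /s",
                                  object$params$branch, object$params$ki))
}

#' @export
autoplot.sts_session <- function(object, ...) {
  tr <- object$truth |>
    tidyr::pivot_longer(c("theta_a", "theta_k", "theta_h"),
                        names_to = "angle", values_to = "deg")
  ggplot2::ggplot(tr, ggplot2::aes(.data$t_s, .data$deg,
                                   colour = .data$angle)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "angle (deg)",
                  title = sprintf("Scripted %s motion (ground truth)",
                                  object$script$direction))
}
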