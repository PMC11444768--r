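# ggplot2 views of the main result types.

#' Plot a percentile time course
#'
#' Percentile of cumulative displacement versus time with a ribbon of
#' +/- 1 SD across replicate percentiles.
#'
#' @param object A `summary_table` from [percentile_timecourse()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot summary_table
#' @export
autoplot.summary_table <- function(object, ...) {
  p <- attr(object, "percentile")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t_h, y = .data$p90_um)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$p90_um - .data$sd_um,
                                      ymax = .data$p90_um + .data$sd_um),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point(shape = 15) +
    ggplot2::labs(x = "time (h)",
                  y = sprintf("p%s cumulative displacement (µm)",
                              if (is.null(p)) "90" else format(p)),
                  title = "Cumulative displacement time course")
}

#' Plot a stiffness-versus-thickness curve
#'
#' Apparent stiffness relative to the half-space value against h/a on a
#' log axis; thin bonded layers read as much stiffer than thick ones.
#'
#' @param object A `stiffness_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot stiffness_curve
#' @export
autoplot.stiffness_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$h_over_a, y = .data$k_ratio)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "thickness / patch radius (h/a)",
                  y = "k / k (half-space)",
                  title = "Apparent stiffness of a bonded elastic layer")
}

#' Plot a displacement field as arrows
#'
#' @param object A `displacement_field` from [track_pair()].
#' @param scale Arrow magnification (default 3, the conventional
#'   visualization factor for small bead displacements).
#' @param ... Unused.
#' @return A ggplot (y axis reversed to match image coordinates).
#' @method autoplot displacement_field
#' @export
autoplot.displacement_field <- function(object, scale = 3, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$x_px, y = .data$y_px,
                               xend = .data$x_px + scale * .data$ux_px,
                               yend = .data$y_px + scale * .data$uy_px,
                               colour = sqrt(.data$ux_um^2 + .data$uy_um^2))) +
    ggplot2::geom_segment(arrow = ggplot2::arrow(length = ggplot2::unit(1.5, "mm"))) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)",
                  colour = "|u| (µm)",
                  title = sprintf("Displacement field (arrows x%g)", scale))
}

#' Plot a z-profile with its thickness fit
#'
#' @param profile A z-profile tibble (`z_um`, `intensity`).
#' @param fit Optional [estimate_thickness()] result; crossings are marked.
#' @return A ggplot.
#' @export
plot_zprofile <- function(profile, fit = NULL) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$z_um, y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "z (µm)", y = "intensity",
                  title = "Confocal z intensity profile")
  if (!is.null(fit)) {
    p <- p +
      ggplot2::geom_vline(xintercept = c(fit$z_up_um, fit$z_down_um),
                          linetype = "dashed") +
      ggplot2::annotate("text",
                        x = mean(c(fit$z_up_um, fit$z_down_um)),
                        y = fit$peak,
                        label = sprintf("%.1f µm", fit$thickness_um),
                        vjust = -0.3)
  }
  p
}
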