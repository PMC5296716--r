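# Figures: day-by-time activity maps (one rectangle per episode, colour
# per category), Poincare scatter with fitted ellipse, and the
# discrimination curve over observation duration.

#' Activity map of one subject
#'
#' Day of measurement on the x-axis, clock time on the (reversed) y-axis;
#' every episode is one colour-coded rectangle at its onset spanning its
#' duration. Midnight-crossing Sleeping episodes are drawn in both day
#' columns.
#'
#' @param episodes Episode table of one subject.
#' @param n_days Days to span on the x-axis (default: last day present).
#' @param palette Named colours per category (default [adl_palette()]).
#' @return A ggplot object.
#' @export
plot_activity_map <- function(episodes, n_days = NULL,
                              palette = adl_palette()) {
  ep <- tibble::as_tibble(episodes)
  n_days <- n_days %||% (if (nrow(ep) > 0) max(ep$day_index) else 1L)
  # draw midnight-crossing episodes in both day columns
  crosses <- ep$onset + ep$duration > 1440
  second <- ep[crosses & ep$day_index + 1 <= n_days, ]
  if (nrow(second) > 0) {
    second$day_index <- second$day_index + 1L
    second$duration <- second$onset + second$duration - 1440
    second$onset <- 0
  }
  ep$duration[crosses] <- 1440 - ep$onset[crosses]
  rect <- dplyr::bind_rows(ep, second)
  p <- ggplot2::ggplot(rect)
  if (nrow(rect) > 0) {
    p <- p + ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$day_index - 0.45, xmax = .data$day_index + 0.45,
      ymin = .data$onset / 60, ymax = (.data$onset + .data$duration) / 60,
      fill = .data$category))
  }
  p +
    ggplot2::scale_fill_manual(values = palette, drop = FALSE,
                               limits = names(palette)) +
    ggplot2::scale_x_continuous(breaks = seq_len(n_days),
                                limits = c(0.5, n_days + 0.5)) +
    ggplot2::scale_y_reverse(breaks = seq(0, 24, 4),
                             labels = sprintf("%02d:00", seq(0, 24, 4)),
                             limits = c(24, 0)) +
    ggplot2::labs(x = "day of measurement", y = "time of day",
                  fill = "ADL") +
    ggplot2::theme_minimal()
}

#' Render an activity map to a figure file
#'
#' @inheritParams plot_activity_map
#' @param path Output file (format from extension, e.g. `.pdf`).
#' @param width,height Device size in inches.
#' @return `path`, invisibly.
#' @export
render_activity_map <- function(episodes, path, n_days = NULL,
                                width = 8, height = 5) {
  p <- plot_activity_map(episodes, n_days = n_days)
  ggplot2::ggsave(path, p, width = width, height = height)
  invisible(path)
}

#' Poincare scatter with identity line and fitted 1-SD ellipse
#'
#' @param pairs Pair tibble from [build_pairs()].
#' @param descriptors Optional [fit_ellipse()] result (computed from
#'   `pairs` when omitted).
#' @return A ggplot object.
#' @export
plot_poincare <- function(pairs, descriptors = NULL) {
  de <- descriptors %||% fit_ellipse(pairs)
  cx <- de$centroid_point[["x"]]
  cy <- de$centroid_point[["y"]]
  th <- seq(0, 2 * pi, length.out = 181)
  u1 <- c(1, 1) / sqrt(2)   # identity-line direction (long axis)
  u2 <- c(-1, 1) / sqrt(2)  # perpendicular (short axis)
  ell <- tibble::tibble(
    x = cx + de$long_axis * cos(th) * u1[1] + de$short_axis * sin(th) * u2[1],
    y = cy + de$long_axis * cos(th) * u1[2] + de$short_axis * sin(th) * u2[2])
  axes <- tibble::tibble(
    x = c(cx - de$long_axis * u1[1], cx - de$short_axis * u2[1]),
    xend = c(cx + de$long_axis * u1[1], cx + de$short_axis * u2[1]),
    y = c(cy - de$long_axis * u1[2], cy - de$short_axis * u2[2]),
    yend = c(cy + de$long_axis * u1[2], cy + de$short_axis * u2[2]),
    axis = c("long", "short"))
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_path(data = ell, colour = "grey40") +
    ggplot2::geom_segment(
      data = axes,
      ggplot2::aes(x = .data$x, xend = .data$xend, y = .data$y,
                   yend = .data$yend, colour = .data$axis)) +
    ggplot2::scale_colour_manual(values = c(long = "blue", short = "red")) +
    ggplot2::annotate("point", x = cx, y = cy, shape = 3, size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "feature on day i", y = "feature on day i + 1",
                  colour = "axis") +
    ggplot2::theme_minimal()
}

#' Discrimination curve over observation duration
#'
#' @param curve Output of [loocv_curve()].
#' @return A ggplot object with one line each for accuracy, sensitivity
#'   and specificity.
#' @export
plot_discrimination_curve <- function(curve) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(curve)[c("day", "sensitivity", "specificity",
                               "accuracy")],
    cols = -"day", names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$day, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "days of measurement", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
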