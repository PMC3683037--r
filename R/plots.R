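# ggplot2 visualizations for tracking results.

#' Plot object trajectories
#'
#' Centroid paths of all tracked objects, colored by identity.
#'
#' @param object A `ram_tracks` object.
#' @param ... Unused.
#' @return A ggplot.  The y axis is reversed so the plot matches image
#'   orientation (y increases downward).
#' @export
#' @method autoplot ram_tracks
autoplot.ram_tracks <- function(object, ...) {
  df <- tidy(object)
  cen <- dplyr::summarise(dplyr::group_by(df, .data$object_id, .data$frame),
                          x = mean(.data$x), y = mean(.data$y),
                          .groups = "drop")
  ggplot2::ggplot(cen, ggplot2::aes(.data$x, .data$y,
                                    color = .data$object_id)) +
    ggplot2::geom_path(linewidth = 0.4) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)", color = "object") +
    ggplot2::theme_minimal()
}

#' @export
plot.ram_tracks <- function(x, ...) print(autoplot(x, ...))

#' Plot contours over a movie frame
#'
#' @param tracks A `ram_tracks` object.
#' @param frame_image The grayscale frame matrix.
#' @param frame Frame index.
#' @return A ggplot.
#' @export
plot_frame_overlay <- function(tracks, frame_image, frame = 1L) {
  df <- tidy(tracks)
  df <- df[df$frame == frame & is.finite(df$x), ]
  img <- tibble::tibble(
    x = rep(seq_len(ncol(frame_image)) - 1L, each = nrow(frame_image)),
    y = rep(seq_len(nrow(frame_image)) - 1L, times = ncol(frame_image)),
    value = as.vector(frame_image))
  ggplot2::ggplot() +
    ggplot2::geom_raster(data = img,
                         ggplot2::aes(.data$x, .data$y,
                                      fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::geom_path(data = df,
                       ggplot2::aes(.data$x, .data$y,
                                    group = .data$object_id,
                                    color = .data$object_id),
                       linewidth = 0.6) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)", color = "object") +
    ggplot2::theme_minimal()
}

#' Plot a relative-position histogram
#'
#' Log-density of one fly's position in another's body frame (x:
#' perpendicular, right of heading positive; y: parallel, ahead positive).
#'
#' @param object A `relpos_histogram` from
#'   [relative_position_histogram()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot relpos_histogram
autoplot.relpos_histogram <- function(object, ...) {
  mids <- (object$breaks[-1] + object$breaks[-length(object$breaks)]) / 2
  df <- expand.grid(y = mids, x = mids)
  df$log_density <- as.vector(object$log_density)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = .data$log_density)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "perpendicular offset (px)",
                  y = "parallel offset (px)",
                  fill = "log10 density") +
    ggplot2::theme_minimal()
}

#' Plot the gliding-speed distribution
#'
#' Histogram of pooled absolute tangential speeds with the fitted
#' exponential density overlaid.
#'
#' @param object A `speed_histogram` from [speed_histogram()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot speed_histogram
autoplot.speed_histogram <- function(object, ...) {
  h <- object$histogram
  df <- tibble::tibble(mid = h$mids, density = h$density)
  xs <- seq(0, max(h$breaks), length.out = 200)
  fit <- tibble::tibble(x = xs, density = dexp(xs, rate = 1 / object$mean))
  ggplot2::ggplot(df, ggplot2::aes(.data$mid, .data$density)) +
    ggplot2::geom_col(width = diff(h$breaks)[1], fill = "grey70") +
    ggplot2::geom_line(data = fit, ggplot2::aes(.data$x, .data$density),
                       color = "red") +
    ggplot2::labs(x = "|gliding speed| (um/min)", y = "density") +
    ggplot2::theme_minimal()
}

#' Plot a tangential-speed trace with reversals
#'
#' @param speeds Tibble from [tangential_speed()] for one object.
#' @return A ggplot with raw and smoothed traces; reversal frames marked.
#' @export
plot_speed_trace <- function(speeds) {
  ggplot2::ggplot(speeds, ggplot2::aes(.data$frame)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$speed_raw),
                       color = "pink", na.rm = TRUE) +
    ggplot2::geom_line(ggplot2::aes(y = .data$speed), color = "red",
                       na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_vline(data = speeds[speeds$reversal, ],
                        ggplot2::aes(xintercept = .data$frame),
                        color = "blue", alpha = 0.4) +
    ggplot2::labs(x = "frame", y = "tangential speed (um/min)") +
    ggplot2::theme_minimal()
}
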