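# broom-style tidiers for tracking results.

#' Tidy tracking results into a long tibble
#'
#' One row per (object, frame, control point), with per-frame flags.
#' Fly tracks additionally carry the Viterbi orientation sign.
#'
#' @param x A `ram_tracks` (or subclass) object.
#' @param ... Unused.
#' @return Tibble with columns object_id, frame, point_index, x, y,
#'   jumped, lost, stunted, exited (and heading_sign for fly tracks).
#' @export
#' @method tidy ram_tracks
tidy.ram_tracks <- function(x, ...) {
  K <- length(x$object_ids)
  out <- vector("list", K)
  n <- x$n_points
  for (k in seq_len(K)) {
    T_ <- x$n_frames
    if (T_ < 1) next
    pts <- x$points[[k]]
    df <- tibble::tibble(
      object_id = x$object_ids[k],
      frame = rep(seq_len(T_), each = n),
      point_index = rep(seq_len(n) - 1L, times = T_),
      x = as.vector(pts[, 1, ]),
      y = as.vector(pts[, 2, ]))
    df$jumped <- x$jumped[k, df$frame]
    df$lost <- x$lost[k, df$frame]
    df$stunted <- x$stunted[k, df$frame]
    df$exited <- !is.na(x$exited_frame[k]) & df$frame >= x$exited_frame[k]
    if (!is.null(x$orientation_sign))
      df$heading_sign <- x$orientation_sign[k, df$frame]
    out[[k]] <- df
  }
  dplyr::bind_rows(out)
}

#' One-row summary of a tracking run
#'
#' @param x A `ram_tracks` object.
#' @param ... Unused.
#' @return Tibble with object/frame counts, solver iteration statistics,
#'   fixed-point residuals and event counts.
#' @export
#' @method glance ram_tracks
glance.ram_tracks <- function(x, ...) {
  tibble::tibble(
    n_objects = length(x$object_ids),
    n_frames = x$n_frames,
    n_points = x$n_points,
    mean_iterations = if (nrow(x$diagnostics)) mean(x$diagnostics$iterations)
      else NA_real_,
    max_residual = if (nrow(x$diagnostics)) max(x$diagnostics$residual)
      else NA_real_,
    n_jumped = sum(x$jumped),
    n_lost = sum(x$lost),
    n_stunted = sum(x$stunted),
    n_exited = sum(!is.na(x$exited_frame)))
}

#' @export
#' @method tidy track_score
tidy.track_score <- function(x, ...) {
  tibble::tibble(n_swaps = x$n_swaps, rmse = x$rmse,
                 fraction_tracked = x$fraction_tracked)
}
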