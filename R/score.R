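# Scoring tracked output against synthetic ground truth.  With a fixed
# number of objects, identity swapping is the only tracking error; swaps are
# counted from persistent changes of each track's nearest truth object.

#' Score tracking output against ground truth
#'
#' Tracks are greedily matched to truth objects at the first common frame
#' (closest pairs first, within `match_radius`).  For every later frame each
#' track's nearest truth object is found; an identity swap is counted when
#' that nearest identity changes and remains changed for at least
#' `persist` consecutive frames (transient mismatches during contact are not
#' swaps).  An exchange between two tracks at the same frame counts as one
#' swap event.  Also reports the per-frame centroid RMSE against the
#' currently assigned truth object and the fraction of track frames within
#' `match_radius` of it.
#'
#' @param tracks A `ram_tracks` object (or a tidy tibble with columns
#'   object_id, frame, x, y giving per-frame centroids).
#' @param truth Ground-truth tibble from the simulators (columns frame,
#'   object, x, y; multiple point rows per object are averaged to a
#'   centroid).
#' @param match_radius Matching radius in pixels.
#' @param persist Frames a changed identity must persist to count as a swap.
#' @return A list of class `track_score`: `n_swaps`, `swap_events` (tibble),
#'   `rmse`, `fraction_tracked`, `per_track` (tibble).
#' @export
score_tracking <- function(tracks, truth, match_radius = 10, persist = 3L) {
  cen <- if (inherits(tracks, "ram_tracks")) {
    tc <- track_centroids(tracks)
    K <- dim(tc)[1]
    dplyr::bind_rows(lapply(seq_len(K), function(k)
      tibble::tibble(object_id = tracks$object_ids[k],
                     frame = seq_len(dim(tc)[3]),
                     x = tc[k, 1, ], y = tc[k, 2, ])))
  } else {
    dplyr::summarise(dplyr::group_by(tracks, .data$object_id, .data$frame),
                     x = mean(.data$x), y = mean(.data$y), .groups = "drop")
  }
  tru <- dplyr::summarise(dplyr::group_by(truth, .data$object, .data$frame),
                          x = mean(.data$x), y = mean(.data$y),
                          .groups = "drop")

  frames <- intersect(unique(cen$frame), unique(tru$frame))
  if (length(frames) == 0)
    stop("tracks and truth share no frames", call. = FALSE)
  f0 <- min(frames)

  c0 <- cen[cen$frame == f0 & is.finite(cen$x), ]
  t0 <- tru[tru$frame == f0, ]
  if (nrow(c0) == 0)
    stop("no track positions at the first common frame", call. = FALSE)
  dmat <- outer(seq_len(nrow(c0)), seq_len(nrow(t0)),
                Vectorize(function(i, j)
                  sqrt((c0$x[i] - t0$x[j])^2 + (c0$y[i] - t0$y[j])^2)))
  assign0 <- rep(NA_integer_, nrow(c0))
  dd <- dmat
  repeat {
    mn <- min(dd)
    if (!is.finite(mn) || mn > match_radius) break
    w <- which(dd == mn, arr.ind = TRUE)[1, , drop = TRUE]
    assign0[w[1]] <- t0$object[w[2]]
    dd[w[1], ] <- Inf
    dd[, w[2]] <- Inf
    if (all(is.finite(assign0))) break
  }
  if (all(is.na(assign0)))
    stop("no truth object within `match_radius` at the first common frame",
         call. = FALSE)

  track_ids <- c0$object_id
  n_tracks <- length(track_ids)
  tru_by_frame <- split(tru, tru$frame)
  cen_by_frame <- split(cen[cen$object_id %in% track_ids, ],
                        cen[cen$object_id %in% track_ids, ]$frame)

  cur <- assign0
  pending <- vector("list", n_tracks)  # candidate new identity + streak
  swap_log <- list()
  se <- 0; n_err <- 0L
  n_in <- 0L; n_tot <- 0L

  for (f in frames) {
    cf <- cen_by_frame[[as.character(f)]]
    tf <- tru_by_frame[[as.character(f)]]
    if (is.null(cf) || is.null(tf)) next
    for (i in seq_len(n_tracks)) {
      row <- cf[cf$object_id == track_ids[i], ]
      if (nrow(row) == 0 || !is.finite(row$x)) next
      d <- sqrt((tf$x - row$x)^2 + (tf$y - row$y)^2)
      nearest <- tf$object[which.min(d)]
      # error vs currently assigned identity
      da <- d[match(cur[i], tf$object)]
      n_tot <- n_tot + 1L
      if (is.finite(da)) {
        se <- se + da^2
        n_err <- n_err + 1L
        if (da <= match_radius) n_in <- n_in + 1L
      }
      if (!is.na(cur[i]) && nearest != cur[i]) {
        p <- pending[[i]]
        if (!is.null(p) && p$id == nearest) {
          p$streak <- p$streak + 1L
        } else {
          p <- list(id = nearest, streak = 1L, frame = f)
        }
        if (p$streak >= persist) {
          swap_log[[length(swap_log) + 1L]] <-
            tibble::tibble(track = track_ids[i], frame = p$frame,
                           from = cur[i], to = p$id)
          cur[i] <- p$id
          p <- NULL
        }
        pending[i] <- list(p)
      } else {
        pending[i] <- list(NULL)
      }
    }
  }

  swaps <- if (length(swap_log)) dplyr::bind_rows(swap_log) else
    tibble::tibble(track = character(), frame = integer(),
                   from = integer(), to = integer())
  # an exchange between two tracks at the same frame is one event:
  # group by (frame, unordered identity pair)
  if (nrow(swaps) > 0) {
    key <- paste(swaps$frame,
                 pmin(swaps$from, swaps$to), pmax(swaps$from, swaps$to))
    n_events <- length(unique(key))
  } else n_events <- 0L

  structure(list(
    n_swaps = n_events,
    swap_events = swaps,
    rmse = if (n_err > 0) sqrt(se / n_err) else NA_real_,
    fraction_tracked = if (n_tot > 0) n_in / n_tot else NA_real_,
    assignment = stats::setNames(assign0, track_ids)
  ), class = "track_score")
}

#' @export
print.track_score <- function(x, ...) {
  cat(sprintf("<track_score: %d swap event(s), RMSE %.3f px, %.1f%% tracked>\n",
              x$n_swaps, x$rmse, 100 * x$fraction_tracked))
  invisible(x)
}
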