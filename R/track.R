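# Block-wise membrane tracking engine shared by the fly and cell pipelines.
# Blocks of `block_size` frames advance by `block_size - block_overlap`;
# frames already solved are pinned, new frames are initialized by carrying
# the last solved slice forward (or linear extrapolation) and then relaxed as
# a spatio-temporal membrane.  Pipeline behavior (tip forces, jump rescue,
# shrink-and-regrow) enters through hooks.

#' Track objects through a movie with the membrane engine
#'
#' Low-level driver used by [track_flies()] and [track_cells()].  Exposed for
#' custom pipelines and for testing.
#'
#' @param n_frames Number of movie frames.
#' @param get_potential `function(frame)` returning the [image_potential()]
#'   of that frame.
#' @param init List of [contour()]s valid on frame 1.
#' @param op Spatial [build_internal_operator()].
#' @param cfg A [solver_config()].
#' @param repulsion Optional [repulsion_params()].
#' @param hooks List of optional callbacks:
#'   `slice_force(k, pts, frame, iter, base_force)` extra per-slice force;
#'   `pre_block(st, blk, frames, new_frames)` returning a possibly modified
#'   [membrane_block()] (e.g. shrink-and-regrow initialization), with access
#'   to the state environment `st`;
#'   `post_block(st, frames, new_frames)` inspect/correct freshly solved
#'   frames (e.g. jump rescue) via `st`.
#' @param img_dim Image dimensions `c(rows, cols)`; objects whose centroid
#'   leaves the image are retired as "exited".
#' @param avg_tangential Apply tangential-force averaging.
#' @return A `ram_tracks` object; see [tidy.ram_tracks()].
#' @export
membrane_track <- function(n_frames, get_potential, init, op, cfg,
                           repulsion = NULL, hooks = list(),
                           img_dim = NULL, avg_tangential = FALSE) {
  K <- length(init)
  ids <- vapply(init, function(c) as.character(c$object_id), character(1))
  n <- op$n
  st <- new.env(parent = emptyenv())
  st$ids <- ids
  st$n_frames <- as.integer(n_frames)
  st$points <- lapply(seq_len(K), function(k)
    array(NA_real_, dim = c(n, 2, max(n_frames, 1L))))
  st$target_length <- vapply(init, function(c) c$target_length, numeric(1))
  st$topology <- op$topology
  st$active <- rep(TRUE, K)
  st$exited_frame <- rep(NA_integer_, K)
  st$jumped <- matrix(FALSE, K, max(n_frames, 1L))
  st$lost <- matrix(FALSE, K, max(n_frames, 1L))
  st$stunted <- matrix(FALSE, K, max(n_frames, 1L))
  st$get_potential <- get_potential
  st$op <- op
  st$cfg <- cfg
  st$repulsion <- repulsion
  st$img_dim <- img_dim
  st$diag <- list()
  st$scratch <- new.env(parent = emptyenv())

  empty_result <- function() {
    structure(list(object_ids = ids, n_frames = as.integer(n_frames),
                   n_points = n, points = st$points,
                   target_length = st$target_length,
                   jumped = st$jumped, lost = st$lost, stunted = st$stunted,
                   exited_frame = st$exited_frame,
                   diagnostics = tibble::tibble(block_start = integer(),
                                                block_end = integer(),
                                                iterations = integer(),
                                                residual = numeric()),
                   cfg = cfg),
              class = "ram_tracks")
  }
  if (n_frames < 1L) return(empty_result())

  slice_force <- hooks$slice_force

  # frame 1: per-frame relaxation from the initial contours
  rel <- relax_frame(init, get_potential(1L), op, cfg,
                     repulsion = repulsion, extra_force = slice_force,
                     avg_tangential = avg_tangential, frame = 1L)
  for (k in seq_len(K)) st$points[[k]][, , 1] <- rel[[k]]$points
  check_exits(st, 1L)

  solved <- 1L
  adv <- cfg$block_size - cfg$block_overlap
  while (solved < n_frames) {
    new_end <- min(solved + adv, n_frames)
    f0 <- max(1L, solved - cfg$block_overlap + 1L)
    frames <- f0:new_end
    new_frames <- (solved + 1L):new_end
    T_ <- length(frames)
    pin <- frames <= solved
    act <- which(st$active)
    if (length(act) == 0) break

    # initialize the block: solved slices from history, new slices predicted
    Xb <- lapply(act, function(k) {
      a <- array(NA_real_, dim = c(n, 2, T_))
      for (ti in seq_len(T_)) {
        f <- frames[ti]
        if (f <= solved) {
          a[, , ti] <- st$points[[k]][, , f]
        } else if (cfg$predict == "linear" && solved >= 2L) {
          a[, , ti] <- st$points[[k]][, , solved] +
            (f - solved) * (st$points[[k]][, , solved] -
                              st$points[[k]][, , solved - 1L])
        } else {
          a[, , ti] <- st$points[[k]][, , solved]
        }
      }
      a
    })
    contours_b <- lapply(act, function(k)
      contour(st$points[[k]][, , solved], target_length = st$target_length[k],
              object_id = ids[k],
              topology = st$topology))
    blk <- membrane_block(contours_b, frames, X = Xb)
    st$block_objects <- act
    if (!is.null(hooks$pre_block))
      blk <- hooks$pre_block(st, blk, frames, new_frames)

    pots <- lapply(frames, get_potential)
    sf <- if (is.null(slice_force)) NULL else function(ki, pts, frame, iter,
                                                       base) {
      slice_force(act[ki], pts, frame, iter, base)
    }
    blk <- solve_membrane_block(blk, pots, op, cfg, pin = pin,
                                repulsion = repulsion, extra_force = sf,
                                avg_tangential = avg_tangential)
    for (ki in seq_along(act)) {
      k <- act[ki]
      for (ti in which(!pin))
        st$points[[k]][, , frames[ti]] <- blk$X[[ki]][, , ti]
    }
    st$diag[[length(st$diag) + 1L]] <-
      list(block_start = frames[1], block_end = new_end,
           iterations = attr(blk, "iterations"),
           residual = attr(blk, "residual"))

    if (!is.null(hooks$post_block))
      hooks$post_block(st, frames, new_frames)
    for (f in new_frames) check_exits(st, f)
    solved <- new_end
  }

  res <- empty_result()
  res$points <- st$points
  res$jumped <- st$jumped
  res$lost <- st$lost
  res$stunted <- st$stunted
  res$exited_frame <- st$exited_frame
  res$diagnostics <- dplyr::bind_rows(lapply(st$diag, tibble::as_tibble))
  res
}

# retire objects whose centroid leaves the image domain at frame f
check_exits <- function(st, f) {
  if (is.null(st$img_dim)) return(invisible())
  h <- st$img_dim[1]; w <- st$img_dim[2]
  for (k in which(st$active)) {
    p <- st$points[[k]][, , f]
    cen <- colMeans(p)
    if (!all(is.finite(cen)) ||
        cen[1] < 0 || cen[1] > w - 1 || cen[2] < 0 || cen[2] > h - 1) {
      st$active[k] <- FALSE
      st$exited_frame[k] <- f
      if (f < st$n_frames)
        st$points[[k]][, , (f + 1):st$n_frames] <- NA_real_
    }
  }
  invisible()
}

#' @export
print.ram_tracks <- function(x, ...) {
  cat(sprintf("<ram_tracks: %d objects x %d frames, %d points/contour>\n",
              length(x$object_ids), x$n_frames, x$n_points))
  if (any(!is.na(x$exited_frame)))
    cat(sprintf("  exited: %d object(s)\n", sum(!is.na(x$exited_frame))))
  invisible(x)
}

#' Per-frame centroids of tracked objects
#'
#' @param tracks A `ram_tracks` object.
#' @return Array `n_objects x 2 x n_frames` of contour centroids (NA after
#'   exit).
#' @export
track_centroids <- function(tracks) {
  K <- length(tracks$object_ids)
  out <- array(NA_real_, dim = c(K, 2, tracks$n_frames))
  for (k in seq_len(K))
    out[k, , ] <- apply(tracks$points[[k]], c(2, 3), mean)
  out
}
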