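# Fly pipeline: rigid oval walkers tracked as 3-point open contours with
# fixed per-object length, Gaussian-smoothed image potentials, jump
# detection and rescue, Viterbi head/tail correction, and the velocity and
# relative-position analyses.

#' Fly tracking configuration
#'
#' @param n_flies Number of objects (fixed for the whole movie).
#' @param fly_length_px,fly_width_px Body dimensions in pixels.
#' @param fps Frame rate (used only for the default flip probability).
#' @param jump_energy_threshold Absolute potential level above which a
#'   contour is considered to sit on empty background.  `NULL` (default)
#'   uses the adaptive rule: depth under the contour below
#'   `jump_depth_fraction` of the object's trailing-median depth.
#' @param jump_depth_fraction Fraction of the typical depth below which a
#'   jump is declared (adaptive rule).
#' @param hmm_flip_prob Per-frame head-flip probability of the orientation
#'   HMM; default `1/(60 * fps)` (jumps on the order of one per minute).
#' @param hmm_velocity_scale Velocity scale (px/frame) of the HMM emission
#'   model.
#' @param alpha,beta Spatial stiffnesses of the 3-point contour.
#' @param k_str Tip-stretching stiffness maintaining the body length.
#' @param blur_sigma Potential smoothing radius; default half the fly
#'   width (steep walls at the body ends keep the tip balance stable).
#' @param r0 Repulsion cutoff; default the fly width.
#' @param epsilon Repulsion magnitude; default the depth of the image
#'   wells of the first frame (background level minus minimum of the
#'   normalized potential), so that repulsion can expel a second contour
#'   from an occupied well.
#' @param rescue_gain Magnitude of the linear attractive force applied to a
#'   jumped fly (pixels of drift per iteration at gamma = 1).
#' @param crowding_rescue Also rescue when two contours crowd one body
#'   while another blob is unclaimed.
#' @param length_mode How the fixed per-object target length is set from the
#'   first frame: `"relaxed"` uses the contour's equilibrium length on the
#'   frame-1 potential, `"extent"` uses the blob's major-axis extent (tips
#'   pressed hard against the body-end walls).
#' @param length_slack Multiplier applied to the relaxed length (mode
#'   `"relaxed"`): slightly above 1 keeps the tips gently engaged with the
#'   body-end ramps, anchoring the contour tangentially without the
#'   escape-prone pressure of the full extent.
#' @param mm_per_px Optional spatial calibration for velocity units.
#' @param solver A [solver_config()]; the fly default uses three-frame
#'   blocks so that contact-time misplacements are corrected within a
#'   couple of frames.
#' @return A list of class `fly_track_config`.
#' @export
fly_track_config <- function(n_flies, fly_length_px, fly_width_px,
                             fps = 30,
                             jump_energy_threshold = NULL,
                             jump_depth_fraction = 0.7,
                             hmm_flip_prob = NULL,
                             hmm_velocity_scale = 1,
                             alpha = 0, beta = 1, k_str = 0.25,
                             blur_sigma = NULL, r0 = NULL, epsilon = NULL,
                             rescue_gain = 2, crowding_rescue = TRUE,
                             mm_per_px = 0.1,
                             length_mode = c("relaxed", "extent"),
                             length_slack = 1,
                             solver = solver_config(block_size = 3)) {
  length_mode <- match.arg(length_mode)
  if (n_flies < 1) stop("`n_flies` must be >= 1", call. = FALSE)
  if (fly_length_px <= 0 || fly_width_px <= 0)
    stop("fly dimensions must be positive", call. = FALSE)
  if (is.null(hmm_flip_prob)) hmm_flip_prob <- 1 / (60 * fps)
  if (hmm_flip_prob <= 0 || hmm_flip_prob >= 0.5)
    stop("`hmm_flip_prob` must be in (0, 0.5)", call. = FALSE)
  if (is.null(blur_sigma)) blur_sigma <- fly_width_px / 2
  if (is.null(r0)) r0 <- fly_width_px
  structure(as.list(environment()), class = "fly_track_config")
}

# dark blobs by contrast-midpoint threshold + connected components; returns
# a tibble of candidate objects sorted by decreasing area.  The midpoint
# between the background level (median) and the darkest pixel stays robust
# when the objects cover only a tiny fraction of the frame, where
# histogram-based thresholds wash out.
detect_blobs <- function(frame, min_area = 4) {
  th <- (median(frame) + min(frame)) / 2
  mask <- frame < th
  lab <- EBImage::bwlabel(mask)
  labs <- as.integer(lab)
  keep <- labs > 0
  if (!any(keep)) return(tibble::tibble())
  idx <- which(matrix(keep, nrow(frame)), arr.ind = TRUE)
  comp <- labs[keep]
  xs <- idx[, 2] - 1; ys <- idx[, 1] - 1
  df <- tibble::tibble(comp = comp, x = xs, y = ys)
  out <- dplyr::group_by(df, .data$comp)
  out <- dplyr::summarise(
    out,
    area = dplyr::n(), cx = mean(.data$x), cy = mean(.data$y),
    sxx = sum((.data$x - mean(.data$x))^2),
    syy = sum((.data$y - mean(.data$y))^2),
    sxy = sum((.data$x - mean(.data$x)) * (.data$y - mean(.data$y))),
    min_x = min(.data$x), max_x = max(.data$x),
    .groups = "drop")
  out <- out[out$area >= min_area, ]
  out <- out[order(-out$area), ]
  # major-axis angle and extent from the pixel covariance
  out$angle <- 0.5 * atan2(2 * out$sxy, out$sxx - out$syy)
  ext <- numeric(nrow(out))
  for (i in seq_len(nrow(out))) {
    sel <- df[df$comp == out$comp[i], ]
    u <- c(cos(out$angle[i]), sin(out$angle[i]))
    proj <- (sel$x - out$cx[i]) * u[1] + (sel$y - out$cy[i]) * u[2]
    ext[i] <- max(proj) - min(proj) + 1
  }
  out$extent <- ext
  out
}

#' Initialize fly contours from the first frame
#'
#' Thresholds the dark blobs, keeps the `n_flies` largest, and places one
#' open 3-point contour along the major axis of each.  The initial target
#' length is the blob's major-axis extent (capped at 1.2x the configured
#' body length); [track_flies()] then calibrates each target to the
#' contour's relaxed equilibrium length on the first frame, after which it
#' stays fixed for the movie.
#'
#' @param frame0 First movie frame.
#' @param cfg A [fly_track_config()].
#' @return List of `n_flies` open [contour()]s.
#' @export
init_flies <- function(frame0, cfg) {
  stopifnot(inherits(cfg, "fly_track_config"))
  blobs <- detect_blobs(frame0)
  if (nrow(blobs) < cfg$n_flies)
    stop(sprintf("initialization found %d blob(s), need %d",
                 nrow(blobs), cfg$n_flies), call. = FALSE)
  blobs <- blobs[seq_len(cfg$n_flies), ]
  lapply(seq_len(cfg$n_flies), function(k) {
    b <- blobs[k, ]
    u <- c(cos(b$angle), sin(b$angle))
    # the known body length bounds the blob extent (merged or blurred blobs
    # otherwise inflate the initial contour)
    ext <- min(b$extent, 1.2 * cfg$fly_length_px)
    h <- (ext - 1) / 2
    pts <- rbind(c(b$cx, b$cy) - h * u,
                 c(b$cx, b$cy),
                 c(b$cx, b$cy) + h * u)
    contour(pts, target_length = ext, object_id = sprintf("fly%02d", k),
            topology = "open")
  })
}

#' Detect a jumped (vanished) object under a relaxed contour
#'
#' A fly that jumped leaves no dark body under its contour, so the mean
#' potential sampled under the control points rises toward the background
#' level.  Returns `TRUE` when the mean potential exceeds `threshold`.
#'
#' @param c A relaxed [contour()].
#' @param potential The frame's [image_potential()].
#' @param threshold Absolute potential threshold (see [fly_track_config()]
#'   for the adaptive default used during tracking).
#' @return Logical.
#' @export
detect_jump <- function(c, potential, threshold) {
  mean(potential_at(potential, c$points)) > threshold
}

# adaptive jump threshold from the trailing depth history of one object:
# halfway (jump_depth_fraction) between the background level and the
# object's typical potential
adaptive_jump_threshold <- function(bg_level, depth_history, frac) {
  med <- median(depth_history)
  bg_level - frac * (bg_level - med)
}

#' Rescue a jumped fly by relaxing it toward an unclaimed blob
#'
#' Adds a constant-magnitude attraction (a global linear potential visible
#' only to the jumped fly) toward the nearest blob not claimed by any other
#' contour, then relaxes normally so the image well captures the contour.
#' Ties between equidistant blobs break deterministically by smaller
#' (row, col) centroid.
#'
#' @param c The jumped [contour()].
#' @param frame The raw frame (for blob detection).
#' @param potential The frame's [image_potential()].
#' @param claimed List of the other objects' contours.
#' @param cfg A [fly_track_config()].
#' @return The rescued contour, or `NULL` when no unclaimed blob exists
#'   (the fly stays lost this frame and is retried on the next).
#' @export
rescue_jumped <- function(c, frame, potential, claimed, cfg) {
  blobs <- detect_blobs(frame)
  if (nrow(blobs) == 0) return(NULL)
  claimed_cen <- t(vapply(claimed, function(cc) colMeans(cc$points),
                          numeric(2)))
  free <- vapply(seq_len(nrow(blobs)), function(i) {
    if (length(claimed) == 0) return(TRUE)
    d <- sqrt((claimed_cen[, 1] - blobs$cx[i])^2 +
                (claimed_cen[, 2] - blobs$cy[i])^2)
    all(d > cfg$r0)
  }, logical(1))
  blobs <- blobs[free, ]
  if (nrow(blobs) == 0) return(NULL)
  cen <- colMeans(c$points)
  d <- sqrt((blobs$cx - cen[1])^2 + (blobs$cy - cen[2])^2)
  ord <- order(d, blobs$cy, blobs$cx)
  target <- c(blobs$cx[ord[1]], blobs$cy[ord[1]])

  op <- build_internal_operator(nrow(c$points), cfg$alpha, cfg$beta, "open")
  cfg2 <- cfg$solver
  cfg2$max_iters <- 400L
  pull <- function(k, pts, frame_idx, iter, base) {
    out <- tip_stretch_points(pts, c$target_length, cfg$k_str)
    to <- target - colMeans(pts)
    dst <- sqrt(sum(to^2))
    if (dst > cfg$fly_width_px / 2)
      out <- out + matrix(cfg$rescue_gain * to / dst, nrow(pts), 2,
                          byrow = TRUE)
    out
  }
  res <- relax_frame(list(c), potential, op, cfg2, extra_force = pull)
  res[[1]]
}

# rebuild a contour object with new points, preserving metadata
contour_from_points <- function(pts, template) {
  template$points <- pts
  template
}

#' Track flies through a movie
#'
#' Runs the repulsive membrane engine with Gaussian-smoothed potentials,
#' 3-point open contours with harmonic tip stretching, jump detection and
#' rescue, and post-hoc Viterbi head-direction correction.
#'
#' @param movie List of grayscale frame matrices (or a frame provider from
#'   [read_movie()]), dark flies on a light background.
#' @param cfg A [fly_track_config()].
#' @return A `fly_tracks` object (subclass of `ram_tracks`) with per-frame
#'   contours, headings, orientation signs and jump flags.  Use
#'   [tidy()] for the point table and [velocity_components()] for
#'   kinematics.
#' @export
track_flies <- function(movie, cfg) {
  stopifnot(inherits(cfg, "fly_track_config"))
  frames <- as_frame_list(movie)
  n_frames <- length(frames)
  if (n_frames == 0) {
    tr <- membrane_track(0L, NULL, list(), build_internal_operator(
      3, cfg$alpha, cfg$beta, "open"), cfg$solver)
    class(tr) <- c("fly_tracks", class(tr))
    return(tr)
  }

  pot_cache <- new.env(parent = emptyenv())
  pot_norm <- NA_real_
  get_potential <- function(f) {
    key <- as.character(f)
    if (!is.null(pot_cache[[key]])) return(pot_cache[[key]])
    p <- gaussian_potential(frames[[f]], cfg$blur_sigma, "dark_objects")
    # normalize the potential (per movie, from frame 1) so the peak image
    # force is ~1 px per iteration at gamma = 1; all other force scales are
    # expressed relative to it
    if (is.na(pot_norm))
      pot_norm <<- max(sqrt(p$gx^2 + p$gy^2), 1e-12)
    p <- image_potential(p$P / pot_norm, sigma = p$sigma)
    # keep the cache small: drop potentials older than one block
    old <- as.integer(ls(pot_cache))
    for (o in old[old < f - cfg$solver$block_size - 1]) {
      rm(list = as.character(o), envir = pot_cache)
    }
    pot_cache[[key]] <- p
    p
  }

  init <- init_flies(frames[[1]], cfg)
  if (is.null(cfg$epsilon)) {
    p1 <- get_potential(1L)
    cfg$epsilon <- median(p1$P) - min(p1$P)
  }
  rep_par <- repulsion_params(cfg$r0, cfg$epsilon)
  op <- build_internal_operator(3, cfg$alpha, cfg$beta, "open")

  depth_hist <- lapply(seq_len(cfg$n_flies), function(k) numeric(0))
  bg_level <- median(get_potential(1L)$P)

  tlen <- vapply(init, function(c) c$target_length, numeric(1))
  slice_force <- function(k, pts, frame, iter, base) {
    tip_stretch_points(pts, tlen[k], cfg$k_str)
  }

  # calibrate each target length to the contour's relaxed length on the
  # first frame: the blob extent only seeds the relaxation, the equilibrium
  # on the actual potential defines the length the tip force maintains.
  # Without this the tips sit under constant outward pressure and leak into
  # the gap when another object approaches.
  pre <- relax_frame(init, get_potential(1L), op, cfg$solver,
                     extra_force = slice_force)
  for (k in seq_len(cfg$n_flies)) {
    if (cfg$length_mode == "relaxed")
      tlen[k] <- cfg$length_slack * polyline_length(pre[[k]]$points)
    init[[k]] <- pre[[k]]
    init[[k]]$target_length <- tlen[k]
  }

  # re-relax frames after a rescue so the correction propagates through
  # the rest of the block
  propagate <- function(st, k, f, new_frames) {
    later <- new_frames[new_frames > f]
    for (f2 in later) {
      relaxed <- relax_frame(
        list(contour(st$points[[k]][, , f2 - 1],
                     target_length = st$target_length[k],
                     object_id = st$ids[k], topology = "open")),
        get_potential(f2), op, cfg$solver,
        extra_force = function(kk, p2, fr, it, b)
          slice_force(k, p2, fr, it, b))
      st$points[[k]][, , f2] <- relaxed[[1]]$points
    }
  }

  post_block <- function(st, block_frames, new_frames) {
    for (f in new_frames) {
      pot <- get_potential(f)
      # depth-based jump detection and rescue
      for (k in which(st$active)) {
        pts <- st$points[[k]][, , f]
        depth <- mean(potential_at(pot, pts))
        thr <- if (!is.null(cfg$jump_energy_threshold))
          cfg$jump_energy_threshold
        else if (length(depth_hist[[k]]) >= 5)
          adaptive_jump_threshold(bg_level, depth_hist[[k]],
                                  cfg$jump_depth_fraction)
        else Inf
        if (depth > thr) {
          others <- lapply(setdiff(which(st$active), k), function(j)
            contour(st$points[[j]][, , f],
                    target_length = st$target_length[j],
                    object_id = st$ids[j], topology = "open"))
          cur <- contour(pts, target_length = st$target_length[k],
                         object_id = st$ids[k], topology = "open")
          res <- rescue_jumped(cur, frames[[f]], pot, others, cfg)
          if (is.null(res)) {
            st$lost[k, f] <- TRUE
          } else {
            st$jumped[k, f] <- TRUE
            st$points[[k]][, , f] <- res$points
            propagate(st, k, f, new_frames)
            depth <- mean(potential_at(pot, res$points))
          }
        }
        depth_hist[[k]] <<- utils::tail(c(depth_hist[[k]], depth), 30)
      }
      # crowding rescue: when two contours share one body while some blob
      # has no contour on it, the shallower of the pair is rescued with the
      # same linear attraction used for jumps
      act <- which(st$active)
      if (cfg$crowding_rescue && length(act) >= 2) {
        cens <- t(vapply(act, function(k) colMeans(st$points[[k]][, , f]),
                         numeric(2)))
        D <- as.matrix(dist(cens))
        diag(D) <- Inf
        crowded <- which(D < cfg$fly_width_px, arr.ind = TRUE)
        if (nrow(crowded) > 0) {
          done <- logical(length(act))
          for (r in seq_len(nrow(crowded))) {
            i <- crowded[r, 1]; j <- crowded[r, 2]
            if (i >= j || done[i] || done[j]) next
            di <- mean(potential_at(pot, st$points[[act[i]]][, , f]))
            dj <- mean(potential_at(pot, st$points[[act[j]]][, , f]))
            loser <- if (di > dj) i else j     # shallower contour moves
            k <- act[loser]
            others <- lapply(setdiff(act, k), function(kk)
              contour(st$points[[kk]][, , f],
                      target_length = st$target_length[kk],
                      object_id = st$ids[kk], topology = "open"))
            cur <- contour(st$points[[k]][, , f],
                           target_length = st$target_length[k],
                           object_id = st$ids[k], topology = "open")
            res <- rescue_jumped(cur, frames[[f]], pot, others, cfg)
            if (!is.null(res)) {
              st$points[[k]][, , f] <- res$points
              st$jumped[k, f] <- TRUE
              propagate(st, k, f, new_frames)
              done[loser] <- TRUE
            }
          }
        }
      }
    }
  }

  tracks <- membrane_track(
    n_frames, get_potential, init, op, cfg$solver,
    repulsion = rep_par,
    hooks = list(slice_force = slice_force, post_block = post_block),
    img_dim = dim(frames[[1]]))

  tracks$config <- cfg
  class(tracks) <- c("fly_tracks", class(tracks))
  tracks <- correct_orientation(tracks, cfg)
  tracks
}

# raw headings (first -> last control point) per object and frame
raw_headings <- function(tracks) {
  K <- length(tracks$object_ids)
  n <- tracks$n_points
  out <- array(NA_real_, dim = c(K, 2, tracks$n_frames))
  for (k in seq_len(K)) {
    d <- tracks$points[[k]][n, , ] - tracks$points[[k]][1, , ]
    nn <- sqrt(colSums(d^2))
    nn[nn == 0] <- 1
    out[k, , ] <- sweep(d, 2, nn, "/")
  }
  out
}

# apply the Viterbi correction, storing per-frame orientation signs
correct_orientation <- function(tracks, cfg) {
  K <- length(tracks$object_ids)
  hd <- raw_headings(tracks)
  cen <- track_centroids(tracks)
  signs <- matrix(1L, K, tracks$n_frames)
  for (k in seq_len(K)) {
    if (tracks$n_frames < 2) break
    v <- cen[k, , 2:tracks$n_frames, drop = FALSE] -
      cen[k, , 1:(tracks$n_frames - 1), drop = FALSE]
    vpar <- c(NA_real_, vapply(seq_len(tracks$n_frames - 1), function(t)
      sum(v[1, , t] * hd[k, , t + 1]), numeric(1)))
    ok <- is.finite(vpar)
    if (sum(ok) < 2) next
    s <- viterbi_head_correction(vpar[ok], tracks$jumped[k, ok],
                                 flip_prob = cfg$hmm_flip_prob,
                                 velocity_scale = cfg$hmm_velocity_scale)
    signs[k, ok] <- s
    # frame 1 inherits the first decoded sign
    first_ok <- which(ok)[1]
    if (first_ok > 1) signs[k, seq_len(first_ok - 1)] <- s[1]
  }
  tracks$orientation_sign <- signs
  tracks$heading <- hd
  tracks
}

#' Viterbi decoding of forward/reversed head orientation
#'
#' Two-state hidden Markov model over per-frame orientation: `+1` (heading
#' as tracked) or `-1` (head and tail exchanged).  Flies mostly walk forward
#' along the head direction, so the emission likelihood of an observed
#' signed parallel velocity `v` under state `s` is a logistic function
#' `sigmoid(s * v / velocity_scale)`.  The flip probability between frames
#' is `flip_prob` except at jump frames, where it is 0.5 (a jump may
#' re-orient the body freely).  Returns the maximum-probability state path.
#'
#' @param v_par Per-frame signed parallel velocity (px/frame), measured
#'   against the uncorrected heading.
#' @param jump_flags Logical vector of the same length.
#' @param flip_prob Per-frame flip probability in (0, 0.5).
#' @param velocity_scale Emission velocity scale (px/frame).
#' @return Integer vector of orientation signs (+1/-1), empty for empty
#'   input.
#' @export
viterbi_head_correction <- function(v_par, jump_flags = NULL,
                                    flip_prob = 1 / 1800,
                                    velocity_scale = 1) {
  m <- length(v_par)
  if (m == 0) return(integer(0))
  if (is.null(jump_flags)) jump_flags <- rep(FALSE, m)
  states <- c(1, -1)
  emit <- function(v, s) plogis(s * v / velocity_scale, log.p = TRUE)
  lp <- matrix(-Inf, 2, m)
  bk <- matrix(0L, 2, m)
  lp[, 1] <- log(0.5) + c(emit(v_par[1], 1), emit(v_par[1], -1))
  for (t in 2:max(m, 2)) {
    if (m < 2) break
    q <- if (jump_flags[t]) 0.5 else flip_prob
    ltrans <- log(matrix(c(1 - q, q, q, 1 - q), 2, 2))
    for (s in 1:2) {
      cand <- lp[, t - 1] + ltrans[, s]
      bk[s, t] <- which.max(cand)
      lp[s, t] <- max(cand) + emit(v_par[t], states[s])
    }
  }
  path <- integer(m)
  path[m] <- which.max(lp[, m])
  if (m >= 2) for (t in (m - 1):1) path[t] <- bk[path[t + 1], t + 1]
  as.integer(states[path])
}

#' Parallel and perpendicular walking-velocity components
#'
#' Centroid displacement per frame projected onto the corrected heading
#' (parallel) and its right-hand normal (perpendicular; with y pointing down
#' the image, "right of heading" is the clockwise normal on screen).
#'
#' @param tracks A `fly_tracks` object.
#' @param mm_per_px,fps Optional calibration; when both are given, a
#'   `v_par_mm_s` / `v_perp_mm_s` pair is added.
#' @return Tibble with object_id, frame, v_par, v_perp (px/frame; frame 1 is
#'   NA).
#' @export
velocity_components <- function(tracks, mm_per_px = NULL, fps = NULL) {
  stopifnot(inherits(tracks, "fly_tracks"))
  cen <- track_centroids(tracks)
  hd <- tracks$heading
  sg <- tracks$orientation_sign
  K <- length(tracks$object_ids)
  out <- vector("list", K)
  for (k in seq_len(K)) {
    T_ <- tracks$n_frames
    vp <- rep(NA_real_, T_); vq <- rep(NA_real_, T_)
    for (t in 2:max(T_, 2)) {
      if (T_ < 2) break
      v <- cen[k, , t] - cen[k, , t - 1]
      h <- hd[k, , t] * sg[k, t]
      if (!all(is.finite(v)) || !all(is.finite(h))) next
      vp[t] <- sum(v * h)
      vq[t] <- sum(v * c(-h[2], h[1]))
    }
    out[[k]] <- tibble::tibble(object_id = tracks$object_ids[k],
                               frame = seq_len(T_), v_par = vp, v_perp = vq)
  }
  res <- dplyr::bind_rows(out)
  if (!is.null(mm_per_px) && !is.null(fps)) {
    res$v_par_mm_s <- res$v_par * mm_per_px * fps
    res$v_perp_mm_s <- res$v_perp * mm_per_px * fps
  }
  res
}

#' Two-dimensional histogram of the relative position of one fly around
#' another
#'
#' For every common frame, the position of fly `b` is expressed in fly `a`'s
#' body frame: x is the perpendicular offset (right of heading positive),
#' y the parallel offset (ahead positive).  Binned counts are normalized to
#' unit total mass and log-scaled with an empty-bin floor.
#'
#' @param tracks A `fly_tracks` object.
#' @param a,b Object ids (or indices) of the reference and the other fly.
#' @param breaks Bin edges in pixels (shared by both axes).
#' @param floor_mass Mass assigned to empty bins before taking the log.
#' @return A list of class `relpos_histogram` with `mass` (sums to 1),
#'   `log_density`, and the bin `breaks`.
#' @export
relative_position_histogram <- function(tracks, a, b,
                                        breaks = seq(-60, 60, by = 4),
                                        floor_mass = 1e-6) {
  stopifnot(inherits(tracks, "fly_tracks"))
  ids <- tracks$object_ids
  ka <- if (is.character(a)) match(a, ids) else a
  kb <- if (is.character(b)) match(b, ids) else b
  cen <- track_centroids(tracks)
  hd <- tracks$heading
  sg <- tracks$orientation_sign
  xs <- c(); ys <- c()
  for (t in seq_len(tracks$n_frames)) {
    pa <- cen[ka, , t]; pb <- cen[kb, , t]
    h <- hd[ka, , t] * sg[ka, t]
    if (!all(is.finite(c(pa, pb, h)))) next
    d <- pb - pa
    ys <- c(ys, sum(d * h))
    xs <- c(xs, sum(d * c(-h[2], h[1])))
  }
  if (length(xs) == 0)
    stop("trajectories share no tracked frames", call. = FALSE)
  cx <- cut(xs, breaks, include.lowest = TRUE)
  cy <- cut(ys, breaks, include.lowest = TRUE)
  keep <- !is.na(cx) & !is.na(cy)
  counts <- table(cy[keep], cx[keep])
  mass <- counts / sum(counts)
  structure(list(mass = as.matrix(mass),
                 log_density = log10(as.matrix(mass) + floor_mass),
                 breaks = breaks, n = sum(counts)),
            class = "relpos_histogram")
}

#' Count close fly-fly contacts
#'
#' Over all frames and unordered pairs, counts the (frame, pair) events with
#' centroid distance below twice the fly width.
#'
#' @param tracks A `fly_tracks` object, or a truth tibble with columns
#'   frame, object, x, y.
#' @param fly_width_px Fly width in pixels.
#' @return Integer contact count.
#' @export
count_contacts <- function(tracks, fly_width_px) {
  if (inherits(tracks, "ram_tracks")) {
    cen <- track_centroids(tracks)
    K <- dim(cen)[1]
    total <- 0L
    for (t in seq_len(dim(cen)[3])) {
      p <- t(cen[, , t])
      p <- p[is.finite(p[, 1]), , drop = FALSE]
      if (nrow(p) < 2) next
      d <- as.matrix(dist(p))
      total <- total + sum(d[upper.tri(d)] < 2 * fly_width_px)
    }
    return(total)
  }
  tru <- dplyr::summarise(dplyr::group_by(tracks, .data$object, .data$frame),
                          x = mean(.data$x), y = mean(.data$y),
                          .groups = "drop")
  total <- 0L
  for (f in unique(tru$frame)) {
    tf <- tru[tru$frame == f, ]
    if (nrow(tf) < 2) next
    d <- as.matrix(dist(cbind(tf$x, tf$y)))
    total <- total + sum(d[upper.tri(d)] < 2 * fly_width_px)
  }
  total
}
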