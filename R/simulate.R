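# Ground-truthed synthetic movie generators for the two imaging regimes the
# tracker targets: dark oval walkers in a light circular arena (persistent
# walking, occasional jumps, frequent near-contact) and bright-field gliding
# rods (dark curved bodies with bright halos, dense packing, tangential
# gliding with Poisson reversals).  All randomness flows from a single seed;
# identical spec + seed gives bit-identical movies and truth tables.

#' Specification of a synthetic fly movie
#'
#' Defaults emulate the recorded arena assays at 0.1 mm/pixel and 30 frames
#' per second, at the denser end of the regimes studied (about 3 flies per
#' square centimeter) so that close contacts are frequent.
#'
#' @param n_objects Number of flies.
#' @param image_size Square frame side in pixels.
#' @param n_frames Number of frames.
#' @param object_length_px,object_width_px Body dimensions in pixels
#'   (2.4 mm x 0.9 mm at 0.1 mm/px).
#' @param speed_mean Mean walking speed, px/frame.
#' @param persistence Heading persistence time in frames.
#' @param jump_rate Per-fly per-frame probability of an escape jump
#'   (about 1 per minute at 30 fps in the recordings; raised here only by
#'   scripted-jump scenarios).
#' @param noise_sigma Additive Gaussian noise, gray levels out of 255.
#' @param arena_radius_px Arena radius; default places `n_objects` at about
#'   3 flies/cm^2.
#' @param contrast Body darkness, gray levels out of 255.
#' @param seed Mandatory RNG seed.
#' @return A list of class `fly_movie_spec`.
#' @export
fly_movie_spec <- function(n_objects = 5, image_size = 256, n_frames = 600,
                           object_length_px = 24, object_width_px = 9,
                           speed_mean = 2, persistence = 20,
                           jump_rate = 1 / 1800, noise_sigma = 10,
                           arena_radius_px = NULL, contrast = 200,
                           seed = 1L) {
  if (is.null(arena_radius_px))
    arena_radius_px <- round(100 * sqrt(n_objects / (3 * pi)))
  stopifnot(n_objects >= 1, n_frames >= 0, object_length_px > 0,
            object_width_px > 0, arena_radius_px > object_length_px)
  structure(as.list(environment()), class = "fly_movie_spec")
}

#' Specification of a synthetic gliding-cell movie
#'
#' Defaults emulate bright-field imaging of a dense monolayer at
#' 0.08 um/pixel and 12 frames/min: dark curved rods with bright halos,
#' gliding along the body axis at a mean speed near 0.5 um/min and reversing
#' direction roughly every 7 minutes.
#'
#' @param n_objects Number of cells.
#' @param image_size Square frame side in pixels.
#' @param n_frames Number of frames.
#' @param object_length_px,object_width_px Cell dimensions in pixels.
#' @param speed_mean Mean gliding speed, px/frame (0.5 px/frame is about
#'   0.5 um/min at the default scale).
#' @param reversal_rate Per-cell per-frame reversal probability.
#' @param curvature_sd Random curvature of laid paths, radians per pixel of
#'   arc.
#' @param noise_sigma Additive Gaussian noise, gray levels out of 255.
#' @param halo_amplitude Brightness of the halo ring, fraction of full scale.
#' @param contrast Body darkness, fraction of full scale.
#' @param background Background gray level, fraction of full scale.
#' @param seed Mandatory RNG seed.
#' @return A list of class `cell_movie_spec`.
#' @export
cell_movie_spec <- function(n_objects = 20, image_size = 192, n_frames = 200,
                            object_length_px = 40, object_width_px = 8,
                            speed_mean = 0.5, reversal_rate = 1 / 84,
                            curvature_sd = 0.02, noise_sigma = 5,
                            halo_amplitude = 0.22, contrast = 0.32,
                            background = 0.55, seed = 1L) {
  stopifnot(n_objects >= 1, n_frames >= 0, object_length_px > 0,
            object_width_px > 0)
  structure(as.list(environment()), class = "cell_movie_spec")
}

# minimum distance from pixels (px, py) to segment a-b, vectorized
point_segment_dist <- function(px, py, a, b) {
  abx <- b[1] - a[1]; aby <- b[2] - a[2]
  len2 <- abx^2 + aby^2
  if (len2 < 1e-18) return(sqrt((px - a[1])^2 + (py - a[2])^2))
  t <- pmin(pmax(((px - a[1]) * abx + (py - a[2]) * aby) / len2, 0), 1)
  sqrt((px - a[1] - t * abx)^2 + (py - a[2] - t * aby)^2)
}

# update a min-distance field D (rows = y, cols = x, 0-based coords) with the
# distance to a polyline, restricted to a bounding box with margin
accumulate_polyline_dist <- function(D, pts, margin) {
  h <- nrow(D); w <- ncol(D)
  x0 <- max(0, floor(min(pts[, 1]) - margin))
  x1 <- min(w - 1, ceiling(max(pts[, 1]) + margin))
  y0 <- max(0, floor(min(pts[, 2]) - margin))
  y1 <- min(h - 1, ceiling(max(pts[, 2]) + margin))
  if (x1 < x0 || y1 < y0) return(D)
  xs <- x0:x1; ys <- y0:y1
  px <- rep(xs, each = length(ys))
  py <- rep(ys, times = length(xs))
  dmin <- rep(Inf, length(px))
  for (i in seq_len(nrow(pts) - 1)) {
    dmin <- pmin(dmin, point_segment_dist(px, py, pts[i, ], pts[i + 1, ]))
  }
  sub <- D[ys + 1, xs + 1, drop = FALSE]
  D[ys + 1, xs + 1] <- pmin(sub, matrix(dmin, length(ys), length(xs)))
  D
}

# quantize to 8-bit grayscale in [0, 1]
quantize8 <- function(img) {
  round(pmin(pmax(img, 0), 1) * 255) / 255
}

#' Simulate a movie of walking flies with ground truth
#'
#' Persistent-random-walk headings inside a hard-wall circular arena with
#' soft-core pairwise exclusion at one body width; jumps teleport the fly by
#' 10-20 body widths with a possible orientation flip.  Rendering draws
#' anti-aliased dark ellipses on a light background, applies a 1 px Gaussian
#' camera PSF, adds Gaussian noise and quantizes to 8-bit levels.
#'
#' @param spec A [fly_movie_spec()].
#' @param seed Optional override of `spec$seed`.
#' @return List of class `synthetic_movie`: `frames` (list of matrices in
#'   `[0, 1]`), `truth` (tibble with frame, object, centroid, body angle,
#'   3-point centerline, jump flag), and the `spec`.
#' @export
simulate_fly_movie <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "fly_movie_spec"))
  if (is.null(seed)) seed <- spec$seed
  withr::with_seed(as.integer(seed), simulate_fly_movie_impl(spec))
}

simulate_fly_movie_impl <- function(spec) {
  K <- spec$n_objects
  sz <- spec$image_size
  ctr <- (sz - 1) / 2
  R <- spec$arena_radius_px
  L <- spec$object_length_px
  W <- spec$object_width_px
  R_eff <- R - L / 2

  # initial non-overlapping placement
  pos <- matrix(NA_real_, K, 2)
  for (k in seq_len(K)) {
    ok <- FALSE
    for (try in 1:500) {
      r <- R_eff * sqrt(runif(1)); a <- runif(1, 0, 2 * pi)
      p <- c(ctr + r * cos(a), ctr + r * sin(a))
      if (k == 1 ||
          min(sqrt(rowSums((pos[seq_len(k - 1), , drop = FALSE] -
                              matrix(p, k - 1, 2, byrow = TRUE))^2))) > L) {
        pos[k, ] <- p; ok <- TRUE; break
      }
    }
    if (!ok) stop("could not place objects without overlap", call. = FALSE)
  }
  theta <- runif(K, 0, 2 * pi)   # walking direction = body axis
  dth <- sqrt(2 / spec$persistence)

  frames <- vector("list", max(spec$n_frames, 0L))
  truth <- vector("list", max(spec$n_frames, 0L))

  for (f in seq_len(spec$n_frames)) {
    jumped <- rep(FALSE, K)
    if (f > 1) {
      theta <- theta + rnorm(K, 0, dth)
      sp <- pmax(0, rnorm(K, spec$speed_mean, 0.4 * spec$speed_mean))
      pos <- pos + sp * cbind(cos(theta), sin(theta))
      # arena wall: slide back inside and steer toward the interior
      for (k in seq_len(K)) {
        d <- pos[k, ] - ctr
        r <- sqrt(sum(d^2))
        if (r > R_eff) {
          pos[k, ] <- ctr + d / r * R_eff
          theta[k] <- atan2(-d[2], -d[1]) + rnorm(1, 0, 0.6)
        }
      }
      # jumps
      for (k in seq_len(K)) {
        if (runif(1) < spec$jump_rate) {
          for (try in 1:100) {
            ang <- runif(1, 0, 2 * pi)
            dist <- runif(1, 10 * W, 20 * W)
            p <- pos[k, ] + dist * c(cos(ang), sin(ang))
            if (sqrt(sum((p - ctr)^2)) > R_eff) next
            others <- pos[-k, , drop = FALSE]
            if (nrow(others) > 0 &&
                min(sqrt(rowSums((others - matrix(p, nrow(others), 2,
                                                  byrow = TRUE))^2))) < 1.5 * W)
              next
            pos[k, ] <- p
            jumped[k] <- TRUE
            if (runif(1) < 0.5) theta[k] <- theta[k] + pi
            break
          }
        }
      }
      # soft-core exclusion at one body width: bodies (centerline segments)
      # may touch but not overlap, whatever the relative orientation
      body_samples <- function(k) {
        u <- c(cos(theta[k]), sin(theta[k]))
        s <- seq(-L / 2, L / 2, length.out = 9)
        cbind(pos[k, 1] + s * u[1], pos[k, 2] + s * u[2])
      }
      for (pass in 1:8) {
        moved <- FALSE
        for (i in seq_len(K - 1)) for (j in (i + 1):K) {
          if (sqrt(sum((pos[j, ] - pos[i, ])^2)) > L + W) next
          bi <- body_samples(i); bj <- body_samples(j)
          dx <- outer(bi[, 1], bj[, 1], `-`)
          dy <- outer(bi[, 2], bj[, 2], `-`)
          dd <- sqrt(dx^2 + dy^2)
          r <- min(dd)
          if (r < W) {
            w_ij <- which(dd == r, arr.ind = TRUE)[1, ]
            push <- c(dx[w_ij[1], w_ij[2]], dy[w_ij[1], w_ij[2]])
            push <- if (r > 1e-9) push / r else c(cos(i + j), sin(i + j))
            shift <- (W - r) / 2
            pos[i, ] <- pos[i, ] + push * shift
            pos[j, ] <- pos[j, ] - push * shift
            moved <- TRUE
          }
        }
        if (!moved) break
      }
    }

    u <- cbind(cos(theta), sin(theta))
    truth[[f]] <- tibble::tibble(
      frame = f, object = seq_len(K),
      x = pos[, 1], y = pos[, 2], angle = theta %% (2 * pi),
      x_head = pos[, 1] + L / 2 * u[, 1], y_head = pos[, 2] + L / 2 * u[, 2],
      x_tail = pos[, 1] - L / 2 * u[, 1], y_tail = pos[, 2] - L / 2 * u[, 2],
      jumped = jumped)
    frames[[f]] <- render_fly_frame(pos, theta, spec)
  }

  structure(list(frames = frames,
                 truth = dplyr::bind_rows(truth),
                 spec = spec, kind = "fly"),
            class = "synthetic_movie")
}

render_fly_frame <- function(pos, theta, spec) {
  sz <- spec$image_size
  bg <- 0.88
  img <- matrix(bg, sz, sz)
  a <- spec$object_length_px / 2
  b <- spec$object_width_px / 2
  dark <- matrix(0, sz, sz)
  for (k in seq_len(nrow(pos))) {
    x0 <- max(0, floor(pos[k, 1] - a - 3)); x1 <- min(sz - 1, ceiling(pos[k, 1] + a + 3))
    y0 <- max(0, floor(pos[k, 2] - a - 3)); y1 <- min(sz - 1, ceiling(pos[k, 2] + a + 3))
    if (x1 < x0 || y1 < y0) next
    xs <- x0:x1; ys <- y0:y1
    px <- rep(xs, each = length(ys)) - pos[k, 1]
    py <- rep(ys, times = length(xs)) - pos[k, 2]
    ca <- cos(theta[k]); sa <- sin(theta[k])
    ub <- (px * ca + py * sa) / a
    vb <- (-px * sa + py * ca) / b
    rho <- sqrt(ub^2 + vb^2)
    cov <- 1 / (1 + exp((rho - 1) / 0.08))
    sub <- dark[ys + 1, xs + 1, drop = FALSE]
    dark[ys + 1, xs + 1] <- pmax(sub, matrix(cov, length(ys), length(xs)))
  }
  img <- img - spec$contrast / 255 * dark
  img <- gaussian_blur(img, 1)
  if (spec$noise_sigma > 0)
    img <- img + matrix(rnorm(sz * sz, 0, spec$noise_sigma / 255), sz, sz)
  quantize8(img)
}

#' Simulate a movie of gliding rod-shaped cells with ground truth
#'
#' Each cell is a worm-like centerline gliding tangentially along a laid
#' path (the tail follows the head's track), with Poisson direction
#' reversals and steric avoidance of neighbors.  Rendering applies a
#' dark-tube intensity profile with a bright halo ring as a function of the
#' distance to the nearest centerline, then adds noise and quantizes.
#'
#' @param spec A [cell_movie_spec()].
#' @param seed Optional override of `spec$seed`.
#' @return A `synthetic_movie` list; `truth` holds 25 resampled centerline
#'   points per cell and frame plus midpoint, gliding sign and reversal
#'   flags.
#' @export
simulate_cell_movie <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cell_movie_spec"))
  if (is.null(seed)) seed <- spec$seed
  withr::with_seed(as.integer(seed), simulate_cell_movie_impl(spec))
}

simulate_cell_movie_impl <- function(spec) {
  K <- spec$n_objects
  sz <- spec$image_size
  L <- spec$object_length_px
  W <- spec$object_width_px
  step <- 1  # arc step of laid paths, px
  margin <- L / 2 + 4

  # lay initial straight-ish paths without overlap
  paths <- vector("list", K)   # each: matrix of points at `step` arc spacing
  s0 <- numeric(K)             # left arc index (1-based, fractional) of body
  dirs <- sample(c(-1, 1), K, TRUE)  # +1: body advances toward path end
  body_pts <- function(k) {
    # body occupies arc [s0, s0 + L]; linear interpolation on path points
    s <- seq(s0[k], s0[k] + L, by = step)
    idx <- s / step + 1
    i0 <- floor(idx); fr <- idx - i0
    p <- paths[[k]]
    i0 <- pmin(pmax(i0, 1), nrow(p) - 1)
    p[i0, , drop = FALSE] * (1 - fr) + p[i0 + 1, , drop = FALSE] * fr
  }
  for (k in seq_len(K)) {
    placed <- FALSE
    for (try in 1:2000) {
      c0 <- runif(2, margin, sz - 1 - margin)
      ang <- runif(1, 0, 2 * pi)
      turns <- cumsum(rnorm(ceiling(3 * L / step), 0, spec$curvature_sd * step))
      angs <- ang + turns
      pts <- matrix(NA_real_, length(angs) + 1, 2)
      pts[1, ] <- c0 - 1.5 * L * c(cos(ang), sin(ang))
      for (i in seq_along(angs))
        pts[i + 1, ] <- pts[i, ] + step * c(cos(angs[i]), sin(angs[i]))
      s_left <- L  # body in the middle third
      sI <- seq(s_left, s_left + L, by = step) / step + 1
      body <- pts[round(sI), , drop = FALSE]
      if (any(body < 2) || any(body > sz - 3)) next
      clash <- FALSE
      if (k > 1) {
        for (j in seq_len(k - 1)) {
          ob <- body_pts(j)
          dmin <- min(proxy_min_dist(body, ob))
          if (dmin < 0.8 * W) { clash <- TRUE; break }
        }
      }
      if (!clash) {
        paths[[k]] <- pts
        s0[k] <- s_left
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("could not place objects without overlap", call. = FALSE)
  }

  base_speed <- rexp(K, rate = 1 / spec$speed_mean)
  heading_extra <- function(p, at_end) {
    # direction for extending the path, with curvature noise
    m <- nrow(p)
    d <- if (at_end) p[m, ] - p[m - 1, ] else p[1, ] - p[2, ]
    atan2(d[2], d[1]) + rnorm(1, 0, spec$curvature_sd * step)
  }

  frames <- vector("list", max(spec$n_frames, 0L))
  truth <- vector("list", max(spec$n_frames, 0L))

  for (f in seq_len(spec$n_frames)) {
    reversed <- rep(FALSE, K)
    if (f > 1) {
      rev_draw <- runif(K) < spec$reversal_rate
      dirs[rev_draw] <- -dirs[rev_draw]
      reversed <- rev_draw
      sp <- base_speed * pmax(0, rnorm(K, 1, 0.2))
      for (k in seq_len(K)) {
        adv <- dirs[k] * sp[k]
        # extend the path if the body would run off it
        while (s0[k] + adv < 0 ||
               (s0[k] + adv + L) / step + 1 > nrow(paths[[k]]) - 1) {
          p <- paths[[k]]
          if (s0[k] + adv < 0) {
            ang <- heading_extra(p, at_end = FALSE)
            newp <- p[1, ] + step * c(cos(ang), sin(ang))
            newp <- steer_clear(newp, p[1, ], k, paths, s0, dirs, L, W, sz,
                                spec, body_pts)
            if (is.null(newp)) { adv <- 0; break }
            paths[[k]] <- rbind(newp, p)
            s0[k] <- s0[k] + step
          } else {
            ang <- heading_extra(p, at_end = TRUE)
            newp <- p[nrow(p), ] + step * c(cos(ang), sin(ang))
            newp <- steer_clear(newp, p[nrow(p), ], k, paths, s0, dirs, L, W,
                                sz, spec, body_pts)
            if (is.null(newp)) { adv <- 0; break }
            paths[[k]] <- rbind(p, newp)
          }
        }
        s0[k] <- max(0, s0[k] + adv)
      }
    }

    bodies <- lapply(seq_len(K), body_pts)
    cl25 <- lapply(bodies, resample_polyline, n = 25)
    truth[[f]] <- dplyr::bind_rows(lapply(seq_len(K), function(k) {
      tibble::tibble(frame = f, object = k,
                     point_index = 0:24,
                     x = cl25[[k]][, 1], y = cl25[[k]][, 2],
                     dir = dirs[k], reversed = reversed[k],
                     speed = if (f > 1) base_speed[k] else 0)
    }))
    frames[[f]] <- render_cell_frame(bodies, spec)
  }

  structure(list(frames = frames, truth = dplyr::bind_rows(truth),
                 spec = spec, kind = "cell"),
            class = "synthetic_movie")
}

# rough min distance between two point sets (used for placement/steering)
proxy_min_dist <- function(a, b) {
  dx <- outer(a[, 1], b[, 1], `-`)
  dy <- outer(a[, 2], b[, 2], `-`)
  sqrt(min(dx^2 + dy^2))
}

# candidate path-extension point: keep inside the frame and away from other
# cells' bodies; try turned alternatives, else NULL (cell stalls)
steer_clear <- function(newp, from, k, paths, s0, dirs, L, W, sz, spec,
                        body_pts_fn) {
  others <- NULL
  for (j in seq_along(paths)) {
    if (j == k) next
    others <- rbind(others, body_pts_fn(j))
  }
  ok <- function(p) {
    if (any(p < 2) || any(p > sz - 3)) return(FALSE)
    if (is.null(others)) return(TRUE)
    min(sqrt((others[, 1] - p[1])^2 + (others[, 2] - p[2])^2)) >= 0.8 * W
  }
  if (ok(newp)) return(newp)
  base_ang <- atan2(newp[2] - from[2], newp[1] - from[1])
  for (dA in c(0.3, -0.3, 0.6, -0.6, 1, -1)) {
    cand <- from + c(cos(base_ang + dA), sin(base_ang + dA))
    if (ok(cand)) return(cand)
  }
  NULL
}

render_cell_frame <- function(bodies, spec) {
  sz <- spec$image_size
  W <- spec$object_width_px
  D <- matrix(Inf, sz, sz)
  for (body in bodies) {
    # thin the polyline to ~3 px segments for speed; distances stay exact
    idx <- unique(c(seq(1, nrow(body), by = 3), nrow(body)))
    D <- accumulate_polyline_dist(D, body[idx, , drop = FALSE], 2.5 * W)
  }
  sig_b <- W / 2.5
  halo_r <- 0.75 * W
  sig_h <- W / 4
  img <- spec$background -
    spec$contrast * exp(-D^2 / (2 * sig_b^2)) +
    spec$halo_amplitude * exp(-(D - halo_r)^2 / (2 * sig_h^2))
  if (spec$noise_sigma > 0)
    img <- img + matrix(rnorm(sz * sz, 0, spec$noise_sigma / 255), sz, sz)
  quantize8(img)
}
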