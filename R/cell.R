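# Cell pipeline: densely packed flexible rods tracked as 25-point open
# contours on enhanced bright-field potentials, with per-timestep
# shrink-and-regrow inchworm placement and gliding-speed/reversal
# statistics.

#' Cell tracking configuration
#'
#' @param cell_width_px Mean cell width in pixels.
#' @param n_points Control points per contour.
#' @param shrink_fraction Length fraction contours are shrunk to at the
#'   start of each new time step before regrowing along the potential
#'   valleys.
#' @param kappa Growth convergence parameter: per iteration the working
#'   target length moves by `kappa * (L0 - L)`.
#' @param k_str Tip-spring stiffness for the anticipated-position
#'   attraction.
#' @param alpha,beta Spatial stiffnesses of the contour.
#' @param hessian_scale Derivative scale of the Hessian features, pixels.
#' @param align_window Window of the alignment order parameter; default
#'   twice the cell width.
#' @param blur_sigma Final blur of the enhanced image; default 3 px.
#' @param weights Enhanced-image weights `c(valley, background, ridge)`.
#' @param valley_shrink Under-segmentation factor for `p_valley`.
#' @param r0 Repulsion cutoff; default 0.7 x cell width.
#' @param epsilon Repulsion magnitude; default the well depth of the
#'   enhanced frame-1 potential.
#' @param speed_smooth_sigma Gaussian smoothing of the speed trace, seconds.
#' @param frame_interval Seconds between frames.
#' @param um_per_px Spatial calibration, micrometers per pixel.
#' @param refit_classifier Refit the pixel classifier every this many frames
#'   (0 = fit once on frame 1 and reuse).
#' @param solver A [solver_config()].
#' @return A list of class `cell_track_config`.
#' @export
cell_track_config <- function(cell_width_px, n_points = 25,
                              shrink_fraction = 0.7, kappa = 0.2,
                              k_str = 0.3, alpha = 0, beta = 0.5,
                              hessian_scale = 1.5, align_window = NULL,
                              blur_sigma = 3,
                              weights = c(valley = 0, background = 0.7,
                                          ridge = 1),
                              valley_shrink = 0.8,
                              r0 = NULL, epsilon = NULL,
                              speed_smooth_sigma = 30, frame_interval = 5,
                              um_per_px = 0.08, refit_classifier = 0,
                              solver = solver_config()) {
  if (n_points < 5) stop("`n_points` must be >= 5", call. = FALSE)
  if (shrink_fraction <= 0 || shrink_fraction > 1)
    stop("`shrink_fraction` must be in (0, 1]", call. = FALSE)
  if (kappa <= 0 || kappa > 1)
    stop("`kappa` must be in (0, 1]", call. = FALSE)
  if (is.null(align_window)) align_window <- 2 * cell_width_px
  if (is.null(r0)) r0 <- 0.7 * cell_width_px
  structure(as.list(environment()), class = "cell_track_config")
}

#' Preprocess one bright-field frame into an enhanced potential
#'
#' Runs the full enhancement chain: Hessian features at `hessian_scale`,
#' alignment order parameter, feature PCA, 3-class EM classification and
#' enhanced-image synthesis.  The fitted classifier (PCA transform + EM
#' parameters) can be reused for later frames of the same movie, in which
#' case only posterior evaluation is performed.
#'
#' @param frame Grayscale frame matrix.
#' @param cfg A [cell_track_config()].
#' @param classifier Optional classifier from a previous call.
#' @return List with `potential` ([image_potential()]), `classmap`
#'   ([pixel_class_map()]) and `classifier`.
#' @export
preprocess_cell_frame <- function(frame, cfg, classifier = NULL) {
  hf <- hessian_features(frame, cfg$hessian_scale)
  ord <- alignment_order(hf, cfg$align_window)
  if (is.null(classifier)) {
    pca <- feature_pca(hf$lam_hi, hf$lam_lo, frame)
    map <- em_classify(pca$pc1, pca$pc2, ord, intensity = frame,
                      lam_hi = hf$lam_hi, valley_shrink = cfg$valley_shrink)
    classifier <- list(pca = pca$transform, em = attr(map, "model"),
                       discarded_variance = pca$discarded_variance)
  } else {
    pcs <- apply_feature_pca(classifier$pca, hf$lam_hi, hf$lam_lo, frame)
    map <- em_classify(pcs$pc1, pcs$pc2, ord, intensity = frame,
                      lam_hi = hf$lam_hi, valley_shrink = cfg$valley_shrink,
                      fit = classifier$em)
  }
  pot <- enhance_image(map, cfg$weights, cfg$blur_sigma)
  list(potential = pot, classmap = map, classifier = classifier)
}

# Morphological thinning of a logical mask to a 1-px skeleton by sequential
# simple-point removal.  A foreground pixel is "simple" when its deletion
# does not change the local 8-connectivity (exactly one 0->1 transition in
# the circular neighbor sequence); endpoints (one neighbor) are kept.
# Sequential deletion preserves connectivity by construction (parallel
# schemes can sever one- and two-pixel diagonal structures); alternating
# north/south/east/west border passes keeps the skeleton centered.
thin_mask <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  m <- matrix(FALSE, h + 2, w + 2)
  m[2:(h + 1), 2:(w + 1)] <- mask
  # circular neighbor offsets: N, NE, E, SE, S, SW, W, NW (rows = y)
  dr <- c(-1, -1, 0, 1, 1, 1, 0, -1)
  dc <- c(0, 1, 1, 1, 0, -1, -1, -1)
  # border direction per pass: background neighbor to the N, S, E, W
  pass_dr <- c(-1, 1, 0, 0)
  pass_dc <- c(0, 0, 1, -1)
  repeat {
    changed <- FALSE
    for (p in 1:4) {
      idx <- which(m, arr.ind = TRUE)
      if (nrow(idx) == 0) break
      border <- !m[cbind(idx[, 1] + pass_dr[p], idx[, 2] + pass_dc[p])]
      idx <- idx[border, , drop = FALSE]
      for (q in seq_len(nrow(idx))) {
        r <- idx[q, 1]; cc <- idx[q, 2]
        if (!m[r, cc]) next
        nb <- m[cbind(r + dr, cc + dc)]
        B <- sum(nb)
        if (B < 2 || B > 6) next
        C <- sum(!nb & c(nb[-1], nb[1]))
        if (C == 1) {
          m[r, cc] <- FALSE
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  m[2:(h + 1), 2:(w + 1)]
}

# longest simple path through a skeleton component: farthest-pair via double
# BFS on the 8-connected pixel graph
skeleton_path <- function(pix) {
  n <- nrow(pix)
  if (n == 1) return(pix)
  key <- paste(pix[, 1], pix[, 2])
  edges <- NULL
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    nb <- paste(pix[, 1] + dx, pix[, 2] + dy)
    hit <- match(nb, key)
    ok <- !is.na(hit)
    if (any(ok))
      edges <- rbind(edges, cbind(which(ok), hit[ok]))
  }
  if (is.null(edges)) return(pix[1, , drop = FALSE])
  g <- igraph::graph_from_edgelist(unique(t(apply(edges, 1, sort))),
                                   directed = FALSE)
  g <- igraph::simplify(g)
  if (igraph::vcount(g) < n)
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
  far1 <- which.max(igraph::bfs(g, root = 1, unreachable = FALSE,
                                dist = TRUE)$dist)
  d2 <- igraph::bfs(g, root = far1, unreachable = FALSE, dist = TRUE)$dist
  far2 <- which.max(d2)
  path <- igraph::shortest_paths(g, from = far1, to = far2)$vpath[[1]]
  pix[as.integer(path), , drop = FALSE]
}

#' Initialize cell contours from a pixel class map
#'
#' Thresholds the valley probability, thins it to a one-pixel skeleton,
#' partitions the skeleton into simple paths (one per connected component,
#' taking the longest path through branched components), and fits one open
#' contour per path.  Paths shorter than half or longer than 1.5 times the
#' median length are discarded.  Each contour's target length is recorded
#' from its initial relaxed length.
#'
#' @param classmap A [pixel_class_map()].
#' @param cfg A [cell_track_config()].
#' @param potential Optional [image_potential()]; when given, contours are
#'   relaxed on it before their target length is recorded.
#' @param valley_threshold Threshold on `p_valley`.
#' @return List of open [contour()]s.
#' @export
init_cells <- function(classmap, cfg, potential = NULL,
                       valley_threshold = 0.5) {
  stopifnot(inherits(classmap, "pixel_class_map"))
  mask <- classmap$p_valley > valley_threshold
  if (!any(mask))
    stop("no valley pixels above threshold; cannot initialize cells",
         call. = FALSE)
  skel <- thin_mask(mask)
  lab <- EBImage::bwlabel(skel)
  labs <- as.integer(lab)
  ncomp <- max(labs)
  paths <- list()
  for (comp in seq_len(ncomp)) {
    idx <- which(matrix(labs == comp, nrow(skel)), arr.ind = TRUE)
    if (nrow(idx) < cfg$n_points / 3) next
    # (x, y) coordinates, 0-based
    pix <- cbind(idx[, 2] - 1, idx[, 1] - 1)
    path <- skeleton_path(pix)
    if (nrow(path) < 3) next
    paths[[length(paths) + 1L]] <- path
  }
  if (length(paths) == 0)
    stop("no usable skeleton paths found", call. = FALSE)
  paths <- bridge_paths(paths, gap = 1.5 * cfg$cell_width_px)
  # paths running through several touching cells are split into
  # single-cell-length pieces; the shrink-and-regrow relaxation then settles
  # each piece into its own valley
  lens <- vapply(paths, polyline_length, numeric(1))
  med <- median(lens)
  split_paths <- list()
  for (p in paths) {
    L <- polyline_length(p)
    # only clearly multi-cell paths are split: single-cell lengths vary by
    # about 20%, so up to 1.7x the median is still one cell
    kseg <- if (L > 1.7 * med) max(2L, round(L / med)) else 1L
    if (kseg == 1L) {
      split_paths[[length(split_paths) + 1L]] <- p
    } else {
      dense <- resample_polyline(p, max(2L * nrow(p), 50L))
      cuts <- round(seq(1, nrow(dense), length.out = kseg + 1L))
      for (s in seq_len(kseg))
        split_paths[[length(split_paths) + 1L]] <-
          dense[cuts[s]:cuts[s + 1], , drop = FALSE]
    }
  }
  paths <- split_paths
  lens <- vapply(paths, polyline_length, numeric(1))
  med <- median(lens)
  # undersegmented fragments are kept down to half of the median; their
  # contours adopt the population median as target length and regrow
  keep <- lens >= 0.5 * med & lens <= 1.5 * med
  paths <- paths[keep]
  contours <- lapply(seq_along(paths), function(k) {
    pts <- resample_polyline(paths[[k]], cfg$n_points)
    contour(pts, object_id = sprintf("cell%03d", k), topology = "open")
  })
  if (!is.null(potential)) {
    # relax onto the valley floor with a provisional length constraint (the
    # skeleton-path length); without tip stretching a free open contour
    # contracts into the deepest point of its valley
    op <- build_internal_operator(cfg$n_points, cfg$alpha, cfg$beta, "open")
    L0s <- vapply(contours, function(c) c$target_length, numeric(1))
    contours <- relax_frame(
      contours, potential, op, cfg$solver,
      extra_force = function(k, pts, fr, it, base)
        tip_stretch_points(pts, L0s[k], cfg$k_str),
      avg_tangential = TRUE)
    contours <- lapply(contours, function(c) {
      c$target_length <- polyline_length(c$points)
      c
    })
    attributes(contours) <- NULL
    # severely undersegmented contours take the population median as their
    # length prior (cell lengths vary within ~20%); inchworm growth extends
    # them along their valley during tracking
    med_len <- median(vapply(contours, function(c) c$target_length,
                             numeric(1)))
    contours <- lapply(contours, function(c) {
      if (c$target_length < 0.7 * med_len) c$target_length <- med_len
      c
    })
  }
  contours
}

# join skeleton paths broken by classification gaps (bright pole caps often
# split one cell body into two valley fragments): endpoints closer than
# `gap` whose end tangents align with the joining direction are bridged
bridge_paths <- function(paths, gap, max_angle = pi / 4) {
  end_tangent <- function(p, head) {
    m <- nrow(p)
    i <- if (head) c(min(4, m), 1) else c(max(1, m - 3), m)
    v <- p[i[2], ] - p[i[1], ]
    v / max(sqrt(sum(v^2)), 1e-12)
  }
  repeat {
    joined <- FALSE
    n <- length(paths)
    if (n < 2) break
    best <- NULL; best_d <- gap
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
      pa <- paths[[a]]; pb <- paths[[b]]
      for (ea in c(TRUE, FALSE)) for (eb in c(TRUE, FALSE)) {
        qa <- if (ea) pa[1, ] else pa[nrow(pa), ]
        qb <- if (eb) pb[1, ] else pb[nrow(pb), ]
        d <- sqrt(sum((qa - qb)^2))
        if (d >= best_d || d < 1e-9) next
        join_dir <- (qb - qa) / d
        ta <- end_tangent(pa, ea)   # points outward at that end
        tb <- end_tangent(pb, eb)
        # outward tangent of a must align with the join direction, and b's
        # outward tangent must oppose it
        if (sum(ta * join_dir) < cos(max_angle)) next
        if (sum(tb * -join_dir) < cos(max_angle)) next
        best <- list(a = a, b = b, ea = ea, eb = eb)
        best_d <- d
      }
    }
    if (is.null(best)) break
    pa <- paths[[best$a]]; pb <- paths[[best$b]]
    if (best$ea) pa <- pa[rev(seq_len(nrow(pa))), , drop = FALSE]
    if (!best$eb) pb <- pb[rev(seq_len(nrow(pb))), , drop = FALSE]
    paths[[best$a]] <- rbind(pa, pb)
    paths[[best$b]] <- NULL
    joined <- TRUE
    if (!joined) break
  }
  paths
}

# shrink a slice about its arc midpoint to `frac` of its length
shrink_points <- function(pts, frac, n) {
  L <- polyline_length(pts)
  lo <- (1 - frac) / 2 * L
  hi <- (1 + frac) / 2 * L
  m <- nrow(pts)
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-m, , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  st <- seq(lo, hi, length.out = n)
  cbind(approx(s, pts[, 1], xout = st)$y,
        approx(s, pts[, 2], xout = st)$y)
}

# inchworm tip force for one slice: grow the working target toward L0,
# split the increment by tip resistance, extrapolate anticipated tip
# positions outward and pull the tips toward them (plus a weak tip stretch
# holding the current working target)
inchworm_tip_force <- function(pts, L0, base_force, cfg, soften) {
  n <- nrow(pts)
  L <- polyline_length(pts)
  dL <- growth_increment(L, L0, cfg$kappa)
  tg <- tip_tangents_points(pts)
  out <- matrix(0, n, 2)
  if (dL > 0) {
    resist <- c(max(0, -sum(base_force[1, ] * tg[1, ])),
                max(0, -sum(base_force[n, ] * tg[2, ])))
    dl2 <- split_growth(dL, resist, soften = soften)
    anticipated <- rbind(pts[1, ] + dl2[1] * tg[1, ],
                         pts[n, ] + dl2[2] * tg[2, ])
    f <- tip_attraction_force(rbind(pts[1, ], pts[n, ]), anticipated,
                              cfg$k_str)
    out[1, ] <- f[1, ]
    out[n, ] <- f[2, ]
  } else {
    # over-length: plain harmonic tip stretching pulls the tips inward
    mag <- cfg$k_str * (L0 - L) / 2
    out[1, ] <- mag * tg[1, ]
    out[n, ] <- mag * tg[2, ]
  }
  out
}

#' Track gliding cells through a bright-field movie
#'
#' Preprocesses every frame into an enhanced potential (classifier fitted on
#' frame 1), initializes 25-point contours from the frame-1 skeleton, and
#' tracks with the repulsive membrane engine.  At the start of every new
#' time step contours are shrunk to `shrink_fraction` of their target length
#' about their midpoint and regrow along the potential valleys during the
#' block iterations (inchworm placement), with the growth increment split
#' between the tips according to the resistant forces.  Tangential force
#' averaging and periodic point redistribution keep the parameterization
#' uniform.
#'
#' @param movie List of frames (or a provider from [read_movie()]).
#' @param cfg A [cell_track_config()].
#' @param corrections Optional tibble of manual corrections (columns frame,
#'   object_id, point_index, x, y) applied between blocks.
#' @return A `cell_tracks` object (subclass of `ram_tracks`).
#' @export
track_cells <- function(movie, cfg, corrections = NULL) {
  stopifnot(inherits(cfg, "cell_track_config"))
  frames <- as_frame_list(movie)
  n_frames <- length(frames)
  op <- build_internal_operator(cfg$n_points, cfg$alpha, cfg$beta, "open")
  if (n_frames == 0) {
    tr <- membrane_track(0L, NULL, list(), op, cfg$solver)
    class(tr) <- c("cell_tracks", class(tr))
    return(tr)
  }

  pre1 <- preprocess_cell_frame(frames[[1]], cfg)
  classifier <- pre1$classifier
  pot_norm <- NA_real_
  pot_cache <- new.env(parent = emptyenv())
  get_potential <- function(f) {
    key <- as.character(f)
    if (!is.null(pot_cache[[key]])) return(pot_cache[[key]])
    p <- if (f == 1L) pre1$potential else {
      cl <- if (cfg$refit_classifier > 0 &&
                (f - 1) %% cfg$refit_classifier == 0) NULL else classifier
      pp <- preprocess_cell_frame(frames[[f]], cfg, cl)
      pp$potential
    }
    if (is.na(pot_norm))
      pot_norm <<- max(sqrt(p$gx^2 + p$gy^2), 1e-12)
    p <- image_potential(p$P / pot_norm, sigma = p$sigma)
    old <- as.integer(ls(pot_cache))
    for (o in old[old < f - cfg$solver$block_size - 1])
      rm(list = as.character(o), envir = pot_cache)
    pot_cache[[key]] <- p
    p
  }

  init <- init_cells(pre1$classmap, cfg, potential = get_potential(1L))
  if (is.null(cfg$epsilon)) {
    p1 <- get_potential(1L)
    cfg$epsilon <- median(p1$P) - min(p1$P)
  }
  rep_par <- repulsion_params(cfg$r0, cfg$epsilon)
  soften <- 0.1 * cfg$epsilon

  tlen <- vapply(init, function(c) c$target_length, numeric(1))
  n <- cfg$n_points

  slice_force <- function(k, pts, frame, iter, base) {
    inchworm_tip_force(pts, tlen[k], base, cfg, soften)
  }

  pre_block <- function(st, blk, block_frames, new_frames) {
    # manual corrections, then shrink the new slices about their midpoint
    for (ki in seq_along(st$block_objects)) {
      k <- st$block_objects[ki]
      for (ti in seq_along(block_frames)) {
        f <- block_frames[ti]
        if (!f %in% new_frames) next
        if (!is.null(corrections)) {
          rows <- corrections[corrections$frame == f &
                                corrections$object_id == st$ids[k], ]
          if (nrow(rows) == n) {
            blk$X[[ki]][, , ti] <-
              as.matrix(rows[order(rows$point_index), c("x", "y")])
            next
          }
        }
        blk$X[[ki]][, , ti] <-
          shrink_points(blk$X[[ki]][, , ti], cfg$shrink_fraction, n)
      }
    }
    blk
  }

  post_block <- function(st, block_frames, new_frames) {
    for (f in new_frames) {
      for (k in which(st$active)) {
        L <- polyline_length(st$points[[k]][, , f])
        if (L < 0.9 * st$target_length[k]) st$stunted[k, f] <- TRUE
      }
    }
  }

  tracks <- membrane_track(
    n_frames, get_potential, init, op, cfg$solver,
    repulsion = rep_par,
    hooks = list(slice_force = slice_force, pre_block = pre_block,
                 post_block = post_block),
    img_dim = dim(frames[[1]]), avg_tangential = TRUE)

  tracks$config <- cfg
  tracks$classifier_variance <- classifier$discarded_variance
  class(tracks) <- c("cell_tracks", class(tracks))
  tracks
}

#' Single-step shrink-and-regrow placement (exposed for testing)
#'
#' Shrinks each contour to `shrink_fraction` of its target length about its
#' arc midpoint, then relaxes with inchworm tip growth until the apparent
#' length returns to the target (or `max_iters`).
#'
#' @param contours List of open [contour()]s carrying target lengths.
#' @param potential An [image_potential()].
#' @param cfg A [cell_track_config()].
#' @return Relaxed contours with restored lengths; attribute `stunted` flags
#'   contours that ended below 90% of target.
#' @export
shrink_regrow_step <- function(contours, potential, cfg) {
  op <- build_internal_operator(cfg$n_points, cfg$alpha, cfg$beta, "open")
  eps <- cfg$epsilon
  if (is.null(eps)) eps <- median(potential$P) - min(potential$P)
  soften <- 0.1 * eps
  shrunk <- lapply(contours, function(c) {
    c$points <- shrink_points(c$points, cfg$shrink_fraction, cfg$n_points)
    c
  })
  tls <- vapply(contours, function(c) c$target_length, numeric(1))
  rep_par <- if (length(contours) > 1) repulsion_params(cfg$r0, eps) else NULL
  out <- relax_frame(shrunk, potential, op, cfg$solver,
                     repulsion = rep_par,
                     extra_force = function(k, pts, fr, it, base)
                       inchworm_tip_force(pts, tls[k], base, cfg, soften),
                     avg_tangential = TRUE)
  stunted <- vapply(seq_along(out), function(k)
    polyline_length(out[[k]]$points) < 0.9 * tls[k], logical(1))
  attr(out, "stunted") <- stunted
  out
}

#' Signed tangential gliding speed and reversal events
#'
#' Projects the per-frame displacement of the contour midpoint onto the
#' local tangent, converts to micrometers per minute, smooths with a
#' Gaussian kernel of `speed_smooth_sigma` seconds, and reports direction
#' reversals as zero-crossings of the smoothed curve.
#'
#' @param tracks A `cell_tracks` object (or `ram_tracks`).
#' @param cfg The [cell_track_config()] (for calibration); defaults to the
#'   config stored in `tracks`.
#' @param object Object id or index; default all objects.
#' @return Tibble with object_id, frame, speed_raw, speed (um/min,
#'   smoothed), and a logical `reversal` marking zero-crossing frames.
#' @export
tangential_speed <- function(tracks, cfg = NULL, object = NULL) {
  if (is.null(cfg)) cfg <- tracks$config
  stopifnot(!is.null(cfg))
  ids <- tracks$object_ids
  sel <- if (is.null(object)) seq_along(ids) else {
    if (is.character(object)) match(object, ids) else object
  }
  mid <- ceiling(tracks$n_points / 2)
  px2um <- cfg$um_per_px
  per_min <- 60 / cfg$frame_interval
  sig_frames <- cfg$speed_smooth_sigma / cfg$frame_interval
  out <- vector("list", length(sel))
  for (si in seq_along(sel)) {
    k <- sel[si]
    T_ <- tracks$n_frames
    raw <- rep(NA_real_, T_)
    for (t in 2:max(T_, 2)) {
      if (T_ < 2) break
      p_now <- tracks$points[[k]][, , t]
      p_prev <- tracks$points[[k]][, , t - 1]
      if (!all(is.finite(p_now)) || !all(is.finite(p_prev))) next
      d <- p_now[mid, ] - p_prev[mid, ]
      tgv <- p_prev[min(mid + 1, tracks$n_points), ] -
        p_prev[max(mid - 1, 1), ]
      tgv <- tgv / sqrt(sum(tgv^2))
      raw[t] <- sum(d * tgv) * px2um * per_min
    }
    sm <- gaussian_smooth_series(raw, sig_frames)
    rev <- rep(FALSE, T_)
    ok <- which(is.finite(sm))
    if (length(ok) > 1) {
      for (i in seq_len(length(ok) - 1)) {
        if (sm[ok[i]] * sm[ok[i + 1]] < 0) rev[ok[i + 1]] <- TRUE
      }
    }
    out[[si]] <- tibble::tibble(object_id = ids[k], frame = seq_len(T_),
                                speed_raw = raw, speed = sm,
                                reversal = rev)
  }
  dplyr::bind_rows(out)
}

# Gaussian smoothing of a series with NA padding at the ends; sigma -> 0
# returns the input
gaussian_smooth_series <- function(x, sigma) {
  if (!is.finite(sigma) || sigma < 1e-9) return(x)
  r <- max(1L, ceiling(3 * sigma))
  kern <- dnorm(seq(-r, r), sd = sigma)
  n <- length(x)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    lo <- max(1, i - r); hi <- min(n, i + r)
    kk <- kern[(lo - i + r + 1):(hi - i + r + 1)]
    xv <- x[lo:hi]
    ok <- is.finite(xv)
    if (any(ok)) out[i] <- sum(xv[ok] * kk[ok]) / sum(kk[ok])
  }
  out
}

#' Pooled gliding-speed distribution and exponential mean
#'
#' Pools the absolute smoothed tangential speeds of all tracked cells over
#' their in-field frames, fits the maximum-likelihood exponential mean (the
#' sample mean), and reports a bootstrap confidence interval and histogram.
#'
#' @param speeds Tibble from [tangential_speed()] (all objects), or a
#'   `cell_tracks` object.
#' @param cfg Config used when `speeds` is a track object.
#' @param n_boot Bootstrap replicates.
#' @param conf Confidence level.
#' @param breaks Histogram breaks (um/min); `NULL` for automatic.
#' @param seed Seed for the bootstrap resampling.
#' @return List of class `speed_histogram`: `mean`, `ci`, `n`, `histogram`.
#' @export
speed_histogram <- function(speeds, cfg = NULL, n_boot = 200, conf = 0.95,
                            breaks = NULL, seed = 1L) {
  if (inherits(speeds, "ram_tracks"))
    speeds <- tangential_speed(speeds, cfg)
  v <- abs(speeds$speed)
  v <- v[is.finite(v)]
  if (length(v) == 0) stop("no finite speed samples", call. = FALSE)
  m <- mean(v)
  ci <- withr::with_seed(as.integer(seed), {
    bs <- replicate(n_boot, mean(sample(v, replace = TRUE)))
    quantile(bs, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  })
  if (is.null(breaks))
    breaks <- seq(0, max(v) * 1.01 + 1e-9, length.out = 30)
  h <- hist(v, breaks = breaks, plot = FALSE)
  structure(list(mean = m, ci = ci, n = length(v), histogram = h),
            class = "speed_histogram")
}

#' @export
print.speed_histogram <- function(x, ...) {
  cat(sprintf(
    "<speed_histogram: n=%d, exponential mean %.3f um/min (CI %.3f-%.3f)>\n",
    x$n, x$mean, x$ci[1], x$ci[2]))
  invisible(x)
}
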