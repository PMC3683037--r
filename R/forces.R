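# External force terms: harmonic tip stretching, tip attraction, inter-object
# repulsion, inchworm growth bookkeeping, and the tangential-force averaging
# optimization.

#' Repulsion parameters
#'
#' @param r0 Cutoff distance in pixels; repulsion is exactly zero at and
#'   beyond `r0`.  Typically the width of the tracked objects (70% of the
#'   width for densely packed rods).
#' @param epsilon Force magnitude scale, chosen to match the depth of the
#'   image-potential wells (default set per movie to the maximum magnitude of
#'   the smoothed image gradient).
#' @return A list of class `repulsion_params`.
#' @export
repulsion_params <- function(r0, epsilon) {
  if (r0 <= 0) stop("`r0` must be positive", call. = FALSE)
  if (epsilon < 0) stop("`epsilon` must be non-negative", call. = FALSE)
  structure(list(r0 = r0, epsilon = epsilon), class = "repulsion_params")
}

#' Harmonic tip-stretching force
#'
#' Maintains the length of an open contour near its target `L0`: each
#' terminus receives `k_str * (L0 - L) / 2` along its outward tangent, so the
#' force elongates when the contour is short and compresses when it is long.
#'
#' @param c An open [contour()].
#' @param k_str Stiffness of the length constraint.
#' @return 2 x 2 matrix of forces (row 1 first tip, row 2 last tip).
#' @export
tip_stretch_force <- function(c, k_str) {
  stopifnot(inherits(c, "contour"))
  if (c$topology != "open")
    stop("tip stretching applies only to open contours", call. = FALSE)
  tg <- tip_tangents(c)
  mag <- k_str * (c$target_length - contour_length(c)) / 2
  mag * tg
}

# matrix-level tip stretching: full n x 2 force with only the tip rows set
tip_stretch_points <- function(pts, L0, k_str) {
  n <- nrow(pts)
  tg <- tip_tangents_points(pts)
  mag <- k_str * (L0 - polyline_length(pts)) / 2
  out <- matrix(0, n, 2)
  out[1, ] <- mag * tg[1, ]
  out[n, ] <- mag * tg[2, ]
  out
}

#' Tip attraction toward anticipated positions
#'
#' A linear spring pulling each terminus toward an externally supplied
#' anticipated position `x*`: force `k_str * (x* - x)`.
#'
#' @param tips 2 x 2 matrix of current tip positions.
#' @param anticipated 2 x 2 matrix of anticipated tip positions.
#' @param k_str Spring stiffness.
#' @return 2 x 2 matrix of forces.
#' @export
tip_attraction_force <- function(tips, anticipated, k_str) {
  k_str * (anticipated - tips)
}

# deterministic pseudo-random unit vector for coincident points, seeded by
# object/point indices; antisymmetric under exchange of the two points so
# the pair forces stay equal and opposite
coincident_direction <- function(a, b, i, j) {
  flip <- (a > b) || (a == b && i > j)
  if (flip) { tmp <- a; a <- b; b <- tmp; tmp <- i; i <- j; j <- tmp }
  h <- sin(a * 12.9898 + b * 78.233 + i * 37.719 + j * 4.581) * 43758.5453
  ang <- 2 * pi * (h - floor(h))
  (if (flip) -1 else 1) * c(cos(ang), sin(ang))
}

#' Short-range repulsion between contours of different objects
#'
#' Every ordered pair of control points (i on object a, j on object b != a)
#' closer than the cutoff `r0` contributes a force on point i of magnitude
#' `epsilon * (1 - d/r0)^2` directed from j toward i, summed over all foreign
#' points.  The profile is continuous with zero value and zero slope at the
#' cutoff.  Forces between a pair of points are equal and opposite, and the
#' total over all objects is zero.  Forces are not normalized by contour
#' length.  The summed force on any point is softly capped near magnitude
#' `epsilon`: when a point's raw sum exceeds the cap, every pair it belongs
#' to is rescaled by the smaller of the two members' cap factors, so several
#' simultaneous neighbors repel no harder than full contact with one
#' (crowded clusters cannot catapult a contour out of its image well) while
#' pair forces remain exactly equal and opposite.
#'
#' Coincident points from different objects (d = 0) are pushed along the
#' displacement since the previous iteration when available, otherwise along
#' a deterministic pseudorandom direction seeded by the object and point
#' indices.
#'
#' @param points_list List of n_k x 2 point matrices, one per object.
#' @param params A [repulsion_params()].
#' @param prev_points_list Optional list of the same shapes holding the
#'   previous-iteration positions (used for the coincident-point fallback).
#' @return List of force matrices matching `points_list`.
#' @export
repulsion_forces <- function(points_list, params, prev_points_list = NULL) {
  stopifnot(inherits(params, "repulsion_params"))
  K <- length(points_list)
  forces <- lapply(points_list, function(p) matrix(0, nrow(p), 2))
  if (K < 2 || params$epsilon == 0) return(forces)
  ns <- vapply(points_list, nrow, integer(1))
  all_pts <- do.call(rbind, points_list)
  obj <- rep.int(seq_len(K), ns)
  pt_idx <- unlist(lapply(ns, seq_len), use.names = FALSE)
  m <- nrow(all_pts)
  r0 <- params$r0; eps <- params$epsilon

  dx <- outer(all_pts[, 1], all_pts[, 1], `-`)
  dy <- outer(all_pts[, 2], all_pts[, 2], `-`)
  d <- sqrt(dx^2 + dy^2)
  foreign <- outer(obj, obj, `!=`)
  act <- foreign & d < r0
  if (!any(act)) return(forces)

  idx <- which(act, arr.ind = TRUE)
  di <- d[idx]
  ux <- dx[idx]; uy <- dy[idx]
  zero <- di < 1e-9
  if (any(zero)) {
    for (k in which(zero)) {
      i <- idx[k, 1]; j <- idx[k, 2]
      dir <- NULL
      if (!is.null(prev_points_list)) {
        prev <- prev_points_list[[obj[i]]][pt_idx[i], ] -
          prev_points_list[[obj[j]]][pt_idx[j], ]
        if (sum(prev^2) > 1e-18) dir <- prev / sqrt(sum(prev^2))
      }
      if (is.null(dir))
        dir <- coincident_direction(obj[i], obj[j], pt_idx[i], pt_idx[j])
      ux[k] <- dir[1]; uy[k] <- dir[2]; di[k] <- 1
    }
  }
  mag <- eps * (1 - pmin(di, r0) / r0)^2
  mag[zero] <- eps
  fx <- mag * ux / di
  fy <- mag * uy / di

  sum_forces <- function(fx, fy) {
    fxs <- rowsum(fx, idx[, 1])
    fys <- rowsum(fy, idx[, 1])
    rows <- as.integer(rownames(fxs))
    total <- matrix(0, m, 2)
    total[rows, 1] <- fxs
    total[rows, 2] <- fys
    total
  }
  total <- sum_forces(fx, fy)
  # soft cap near epsilon: rescale each pair by the smaller of its two
  # members' cap factors (keeps pair forces equal and opposite)
  mags <- sqrt(rowSums(total^2))
  if (any(mags > eps)) {
    sfac <- pmin(1, eps / pmax(mags, 1e-300))
    fac <- pmin(sfac[idx[, 1]], sfac[idx[, 2]])
    total <- sum_forces(fx * fac, fy * fac)
  }
  off <- c(0L, cumsum(ns))
  for (k in seq_len(K))
    forces[[k]] <- total[(off[k] + 1):off[k + 1], , drop = FALSE]
  forces
}

#' Inchworm growth increment
#'
#' Per-iteration adjustment of the working target length while a shrunk
#' contour regrows: `dL = kappa * (L0 - L_now)`, so repeated application
#' converges geometrically to `L0` with rate `1 - kappa`.
#'
#' @param L_now Current apparent length (pixels).
#' @param L0 Normal (target) length (pixels).
#' @param kappa Convergence parameter in (0, 1].
#' @return Length increment in pixels.
#' @export
growth_increment <- function(L_now, L0, kappa) {
  if (any(L_now <= 0)) stop("`L_now` must be positive", call. = FALSE)
  kappa * (L0 - L_now)
}

#' Split tip growth by resistance
#'
#' Distributes a total length increment between the two termini inversely to
#' the resistant forces opposing outward growth, in analogy with a
#' one-dimensional watershed where boundary expansion is inversely
#' proportional to the local steepness:
#' `dL_i = dL * (1/(c + resist_i)) / sum_j (1/(c + resist_j))`.
#' The two shares always sum to `dL`; a blocked tip (large resistance)
#' receives proportionally less growth.
#'
#' @param dL Total growth (>= 0, pixels).
#' @param resist Length-2 vector of non-negative resistances (the tangential
#'   components of image plus repulsive force opposing outward growth at each
#'   tip).
#' @param soften Softening constant `c > 0` keeping the split finite at zero
#'   resistance.
#' @return Length-2 vector of per-tip growth.
#' @export
split_growth <- function(dL, resist, soften = 0.1) {
  if (dL < 0) stop("`dL` must be non-negative", call. = FALSE)
  if (length(resist) != 2 || any(resist < 0))
    stop("`resist` must be two non-negative scalars", call. = FALSE)
  w <- 1 / (soften + resist)
  dL * w / sum(w)
}

#' Replace tangential force components by their contour average
#'
#' The tangential component of the force at each control point is projected
#' out and replaced by the mean tangential component along the contour
#' (re-applied along each point's local tangent).  Normal components are
#' untouched.  This smooths tangential point motion without changing the
#' contour's normal dynamics.
#'
#' @param points n x 2 point matrix (or a [contour()]).
#' @param forces n x 2 force matrix aligned with the points.
#' @return n x 2 adjusted force matrix.
#' @export
average_tangential_force <- function(points, forces) {
  if (inherits(points, "contour")) points <- points$points
  tg <- point_tangents(points)
  f_tan <- rowSums(forces * tg)
  forces - f_tan * tg + mean(f_tan) * tg
}
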