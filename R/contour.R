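#' Construct an active contour
#'
#' A contour is an ordered set of control points tracing one object in one
#' frame.  Coordinates are in pixel units with `x` = column and `y` = row,
#' 0-based and pixel-centered.  Open contours model elongated objects with
#' free tips and a fixed target length; closed contours model area
#' boundaries.
#'
#' @param points Numeric n x 2 matrix (columns `x`, `y`) of control points.
#' @param target_length Target contour length L0 in pixels.  Defaults to the
#'   current polyline length.  Must stay constant across frames for a given
#'   object.
#' @param object_id Opaque identifier for the tracked object.
#' @param topology `"open"` or `"closed"`.
#' @return An object of class `contour`.
#' @export
#' @examples
#' c1 <- contour(cbind(x = c(0, 3, 6), y = c(0, 0, 0)))
#' contour_length(c1)
contour <- function(points, target_length = NULL, object_id = "obj1",
                    topology = c("open", "closed")) {
  topology <- match.arg(topology)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 2L)
    stop("`points` must be an n x 2 matrix (x, y)", call. = FALSE)
  n <- nrow(points)
  n_min <- if (topology == "open") 3L else 4L
  if (n < n_min)
    stop(sprintf("%s contours need at least %d points, got %d",
                 topology, n_min, n), call. = FALSE)
  if (!all(is.finite(points)))
    stop("contour points must be finite", call. = FALSE)
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                         points[-n, , drop = FALSE])^2))
  if (any(seg == 0))
    stop("consecutive contour points must be distinct", call. = FALSE)
  if (is.null(target_length))
    target_length <- polyline_length(points, closed = topology == "closed")
  if (!is.finite(target_length) || target_length <= 0)
    stop("`target_length` must be a positive number", call. = FALSE)
  colnames(points) <- c("x", "y")
  structure(
    list(points = points, target_length = as.numeric(target_length),
         object_id = object_id, topology = topology),
    class = "contour"
  )
}

#' @export
print.contour <- function(x, ...) {
  cat(sprintf("<contour '%s': %d points, %s, length %.2f px (target %.2f)>\n",
              x$object_id, nrow(x$points), x$topology,
              contour_length(x), x$target_length))
  invisible(x)
}

# polyline length of a raw point matrix
polyline_length <- function(points, closed = FALSE) {
  n <- nrow(points)
  d <- sum(sqrt(rowSums((points[-1, , drop = FALSE] -
                           points[-n, , drop = FALSE])^2)))
  if (closed)
    d <- d + sqrt(sum((points[1, ] - points[n, ])^2))
  d
}

#' Contour length
#'
#' Sum of consecutive control-point distances, plus the closing segment for
#' closed topology.
#'
#' @param c A [contour()].
#' @return Length in pixels.
#' @export
contour_length <- function(c) {
  stopifnot(inherits(c, "contour"))
  polyline_length(c$points, closed = c$topology == "closed")
}

# resample a raw open polyline to n points at equal arc spacing
resample_polyline <- function(points, n) {
  m <- nrow(points)
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                         points[-m, , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  L <- s[m]
  if (L <= 0) stop("degenerate polyline: zero length", call. = FALSE)
  # strictly increasing knots (drop duplicated arc positions)
  keep <- c(TRUE, diff(s) > 0)
  s2 <- s[keep]
  p2 <- points[keep, , drop = FALSE]
  st <- seq(0, L, length.out = n)
  cbind(x = approx(s2, p2[, 1], xout = st)$y,
        y = approx(s2, p2[, 2], xout = st)$y)
}

#' Redistribute control points at uniform arc spacing
#'
#' Places the same number of control points at equal arc-length spacing along
#' the current polyline.  Endpoints of open contours are preserved.  Applied
#' periodically during relaxation so tangential motion does not bunch points.
#'
#' @param c A [contour()].
#' @return A `contour` with uniformly spaced points.
#' @export
resample_uniform <- function(c) {
  stopifnot(inherits(c, "contour"))
  pts <- c$points
  n <- nrow(pts)
  if (c$topology == "open") {
    new <- resample_polyline(pts, n)
  } else {
    closed_pts <- rbind(pts, pts[1, , drop = FALSE])
    m <- n + 1L
    seg <- sqrt(rowSums((closed_pts[-1, , drop = FALSE] -
                           closed_pts[-m, , drop = FALSE])^2))
    s <- c(0, cumsum(seg))
    L <- s[m]
    if (L <= 0) stop("degenerate polyline: zero length", call. = FALSE)
    st <- seq(0, L, length.out = n + 1L)[seq_len(n)]
    new <- cbind(x = approx(s, closed_pts[, 1], xout = st)$y,
                 y = approx(s, closed_pts[, 2], xout = st)$y)
  }
  c$points <- new
  c
}

#' Outward unit tangents at the tips of an open contour
#'
#' The tangential directions at each terminus pointing away from the contour
#' body: at the first point away from the second, at the last point away from
#' the second-to-last.
#'
#' @param c An open [contour()].
#' @return A 2 x 2 matrix; row 1 is the tangent at the first point, row 2 at
#'   the last, each a unit vector.
#' @export
tip_tangents <- function(c) {
  stopifnot(inherits(c, "contour"))
  if (c$topology != "open")
    stop("tip tangents are defined only for open contours", call. = FALSE)
  tip_tangents_points(c$points)
}

# matrix-level version used in inner loops
tip_tangents_points <- function(pts) {
  n <- nrow(pts)
  t1 <- pts[1, ] - pts[2, ]
  t2 <- pts[n, ] - pts[n - 1, ]
  t1 <- t1 / sqrt(sum(t1^2))
  t2 <- t2 / sqrt(sum(t2^2))
  rbind(first = t1, last = t2)
}

# unit tangents at every point (central differences; one-sided at open ends)
point_tangents <- function(pts) {
  n <- nrow(pts)
  d <- rbind(pts[2, ] - pts[1, ],
             pts[3:n, , drop = FALSE] - pts[1:(n - 2), , drop = FALSE],
             pts[n, ] - pts[n - 1, ])
  nn <- sqrt(rowSums(d^2))
  nn[nn == 0] <- 1
  d / nn
}

#' @export
#' @method as_tibble contour
as_tibble.contour <- function(x, ...) {
  pts <- x$points
  tibble::tibble(
    object_id = x$object_id,
    point_index = seq_len(nrow(pts)) - 1L,
    x = pts[, 1],
    y = pts[, 2]
  )
}

#' @export
#' @method tidy contour
tidy.contour <- function(x, ...) as_tibble.contour(x)
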