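# Image potentials: smoothed scalar fields whose minima sit on the objects.
# The negative gradient of the potential is the image force that pulls
# contours onto features.  Coordinates follow the package convention:
# x = column, y = row, 0-based, pixel centers at integers; a matrix element
# [i, j] (1-based R indexing) sits at (x, y) = (j - 1, i - 1).

# separable Gaussian blur with replicated borders
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  g <- dnorm(seq(-r, r), sd = sigma)
  g <- g / sum(g)
  EBImage::filter2(img, outer(g, g), boundary = "replicate")
}

# central-difference gradient; border gradients are zero (no force pulls a
# contour across the image edge)
field_gradient <- function(P) {
  h <- nrow(P); w <- ncol(P)
  gx <- matrix(0, h, w)
  gy <- matrix(0, h, w)
  if (w >= 3)
    gx[, 2:(w - 1)] <- (P[, 3:w] - P[, 1:(w - 2)]) / 2
  if (h >= 3)
    gy[2:(h - 1), ] <- (P[3:h, ] - P[1:(h - 2), ]) / 2
  list(gx = gx, gy = gy)
}

#' Create an image potential from a scalar field
#'
#' Wraps a scalar field with its precomputed gradient force field.  Minima of
#' the field should coincide with the objects so that the image force
#' `-grad P` attracts contours onto them.
#'
#' @param P Numeric matrix (rows = y, columns = x).
#' @param sigma Smoothing radius in pixels recorded as metadata.
#' @return An object of class `image_potential` with fields `P`, `gx`, `gy`,
#'   `sigma`, `dim`.
#' @export
image_potential <- function(P, sigma = NA_real_) {
  if (!all(is.finite(P)))
    stop("image potential contains non-finite pixels", call. = FALSE)
  g <- field_gradient(P)
  structure(list(P = P, gx = g$gx, gy = g$gy, sigma = sigma, dim = dim(P)),
            class = "image_potential")
}

#' @export
print.image_potential <- function(x, ...) {
  cat(sprintf("<image_potential %d x %d, sigma=%.2g, range [%.3g, %.3g]>\n",
              x$dim[1], x$dim[2], x$sigma, min(x$P), max(x$P)))
  invisible(x)
}

#' Gaussian-smoothed image potential
#'
#' Blurs a grayscale frame so the image force field varies smoothly, and
#' orients it so that objects sit in potential minima: dark objects on a
#' light background are used as-is, bright objects negate the field.
#'
#' @param frame Grayscale image matrix, any finite range.
#' @param sigma Blur radius in pixels (typically the object width).
#' @param polarity `"dark_objects"` or `"bright_objects"`.
#' @return An [image_potential()].
#' @export
gaussian_potential <- function(frame, sigma,
                               polarity = c("dark_objects",
                                            "bright_objects")) {
  polarity <- match.arg(polarity)
  if (sigma <= 0) stop("`sigma` must be positive", call. = FALSE)
  if (!all(is.finite(frame)))
    stop("frame contains non-finite pixels", call. = FALSE)
  P <- gaussian_blur(frame, sigma)
  if (polarity == "bright_objects") P <- -P
  image_potential(P, sigma = sigma)
}

# bilinear interpolation of a field at continuous (x, y) pixel coordinates,
# clamped to the image domain
bilinear <- function(field, x, y) {
  h <- nrow(field); w <- ncol(field)
  x <- pmin(pmax(x, 0), w - 1)
  y <- pmin(pmax(y, 0), h - 1)
  x0 <- pmin(floor(x), w - 2); x0 <- pmax(x0, 0)
  y0 <- pmin(floor(y), h - 2); y0 <- pmax(y0, 0)
  fx <- x - x0; fy <- y - y0
  i0 <- y0 + 1; j0 <- x0 + 1
  f00 <- field[cbind(i0, j0)]
  f01 <- field[cbind(i0, j0 + 1)]
  f10 <- field[cbind(i0 + 1, j0)]
  f11 <- field[cbind(i0 + 1, j0 + 1)]
  (1 - fy) * ((1 - fx) * f00 + fx * f01) + fy * ((1 - fx) * f10 + fx * f11)
}

#' Image force at contour points
#'
#' Evaluates `-grad P` at each point by bilinear interpolation of the
#' precomputed gradient fields.  Points outside the image are clamped to the
#' border, where the gradient is zero (no force outside the field of view).
#'
#' @param potential An [image_potential()].
#' @param points n x 2 matrix of (x, y) positions.
#' @return n x 2 matrix of force vectors.
#' @export
image_force <- function(potential, points) {
  stopifnot(inherits(potential, "image_potential"))
  cbind(-bilinear(potential$gx, points[, 1], points[, 2]),
        -bilinear(potential$gy, points[, 1], points[, 2]))
}

# potential values under points (used for jump detection)
potential_at <- function(potential, points) {
  bilinear(potential$P, points[, 1], points[, 2])
}
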