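# shared fixtures: tiny analytic potentials and random contours

# quadratic bowl potential centered at (cx, cy)
bowl_potential <- function(size = 64, cx = 30, cy = 25, scale = 200) {
  P <- outer(0:(size - 1), 0:(size - 1),
             function(y, x) ((x - cx)^2 + (y - cy)^2) / scale)
  image_potential(P)
}

# two Gaussian wells at distance `sep`, depth 1, width `sigma`
double_well_potential <- function(size = 96, sep = 12, sigma = 5,
                                  depth = 1) {
  cx1 <- (size - 1) / 2 - sep / 2
  cx2 <- (size - 1) / 2 + sep / 2
  cy <- (size - 1) / 2
  P <- outer(0:(size - 1), 0:(size - 1), function(y, x)
    -depth * exp(-((x - cx1)^2 + (y - cy)^2) / (2 * sigma^2)) -
      depth * exp(-((x - cx2)^2 + (y - cy)^2) / (2 * sigma^2)))
  list(potential = image_potential(P),
       wells = rbind(c(cx1, cy), c(cx2, cy)))
}

# Gaussian-smooth a raw matrix (for constructing smooth test images)
gaussian_blur_probe <- function(img, sigma) {
  ramtrack:::gaussian_blur(img, sigma)
}

# interpolate a potential's scalar field at continuous coordinates
bilinear_probe <- function(pot, x, y) {
  ramtrack:::bilinear(pot$P, x, y)
}

# random open contour with n points, roughly unit spacing
random_contour <- function(n, seed = 1, id = "r1") {
  withr::with_seed(seed, {
    steps <- cbind(rnorm(n - 1, 1, 0.2), rnorm(n - 1, 0, 0.4))
    pts <- rbind(c(20, 20), c(20, 20) + apply(steps, 2, cumsum))
    contour(pts, object_id = id)
  })
}

# straight uniformly spaced contour
straight_contour <- function(n, spacing = 2, angle = 0, origin = c(10, 10)) {
  u <- c(cos(angle), sin(angle))
  pts <- t(vapply(seq_len(n) - 1,
                  function(i) origin + i * spacing * u, numeric(2)))
  contour(pts, object_id = "s1")
}

# two-channel (Fig. 5-like) potential: two parallel valleys separated by a
# ridge along y; valleys at x = xc +- half_gap
two_channel_potential <- function(size = 80, half_gap = 6, valley_sigma = 2,
                                  ridge_height = 0.8) {
  xc <- (size - 1) / 2
  P <- outer(0:(size - 1), 0:(size - 1), function(y, x) {
    v1 <- -exp(-((x - (xc - half_gap))^2) / (2 * valley_sigma^2))
    v2 <- -exp(-((x - (xc + half_gap))^2) / (2 * valley_sigma^2))
    r <- ridge_height * exp(-((x - xc)^2) / (2 * valley_sigma^2))
    0.7 + v1 + v2 + r
  })
  list(potential = image_potential(P), x_valleys = c(xc - half_gap,
                                                     xc + half_gap),
       x_ridge = xc)
}
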