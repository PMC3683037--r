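# Bright-field preprocessing: Hessian ridge/valley features, a nematic
# alignment order parameter, principal-component projection of the
# eigenvalue-intensity space, 3-class EM pixel classification and synthesis
# of an enhanced image whose valleys sit on cell bodies, ridges on the bright
# halos and whose background is elevated so contours cannot leak off cells.

# sampled Gaussian-derivative kernels with moment corrections so that
# correlation with polynomial images reproduces exact derivatives:
# g: sum 1;  g1: sum 0, first moment 1;  g2: sum 0, odd moments 0 (by
# symmetry), second moment 2.
deriv_kernels <- function(sigma) {
  r <- max(2L, ceiling(4 * sigma))
  u <- seq(-r, r)
  g <- dnorm(u, sd = sigma); g <- g / sum(g)
  g1 <- -u / sigma^2 * dnorm(u, sd = sigma)
  g1 <- g1 - mean(g1)
  g1 <- g1 / sum(g1 * u)                 # correlation(I = x) -> 1
  g2 <- (u^2 - sigma^2) / sigma^4 * dnorm(u, sd = sigma)
  g2 <- g2 - mean(g2)
  g2 <- g2 * 2 / sum(g2 * u^2)           # correlation(I = x^2) -> 2
  list(g = g, g1 = g1, g2 = g2)
}

#' Gaussian-derivative Hessian features of a frame
#'
#' Computes the per-pixel 2 x 2 Hessian of the image at the given derivative
#' scale and its eigen-decomposition.  `lam_hi` is the eigenvalue of larger
#' magnitude, `lam_lo` the other; `orient` (fields `ox`, `oy`) is the unit
#' eigenvector of `lam_hi` with sign canonicalized to the upper half-plane.
#' Dark line-like cell bodies produce strongly positive `lam_hi` across the
#' body; bright halos produce strongly negative values.
#'
#' @param frame Grayscale image matrix.
#' @param scale Derivative scale in pixels (about the half-width of the
#'   features of interest).
#' @return An object of class `hessian_features` with matrices `lam_hi`,
#'   `lam_lo`, `ox`, `oy`, `ixx`, `iyy`, `ixy` and the `scale`.
#' @export
hessian_features <- function(frame, scale) {
  if (scale <= 0) stop("`scale` must be positive", call. = FALSE)
  kk <- deriv_kernels(scale)
  # rows = y, cols = x: outer(row kernel, col kernel)
  Ixx <- EBImage::filter2(frame, outer(kk$g, kk$g2), boundary = "replicate")
  Iyy <- EBImage::filter2(frame, outer(kk$g2, kk$g), boundary = "replicate")
  Ixy <- EBImage::filter2(frame, outer(kk$g1, kk$g1), boundary = "replicate")
  tr2 <- (Ixx + Iyy) / 2
  det_root <- sqrt(((Ixx - Iyy) / 2)^2 + Ixy^2)
  l1 <- tr2 + det_root
  l2 <- tr2 - det_root
  hi_is_l1 <- abs(l1) >= abs(l2)
  lam_hi <- ifelse(hi_is_l1, l1, l2)
  lam_lo <- ifelse(hi_is_l1, l2, l1)
  # eigenvector of lam_hi: rows of (H - lam_lo I) span it; pick the more
  # stable of the two analytic forms
  vx1 <- Ixy;            vy1 <- lam_hi - Ixx
  vx2 <- lam_hi - Iyy;   vy2 <- Ixy
  use1 <- (vx1^2 + vy1^2) >= (vx2^2 + vy2^2)
  ox <- ifelse(use1, vx1, vx2)
  oy <- ifelse(use1, vy1, vy2)
  nrm <- sqrt(ox^2 + oy^2)
  degen <- nrm < 1e-12
  ox <- ifelse(degen, 1, ox / pmax(nrm, 1e-12))
  oy <- ifelse(degen, 0, oy / pmax(nrm, 1e-12))
  flip <- oy < 0 | (oy == 0 & ox < 0)
  ox <- ifelse(flip, -ox, ox)
  oy <- ifelse(flip, -oy, oy)
  structure(list(lam_hi = lam_hi, lam_lo = lam_lo, ox = ox, oy = oy,
                 ixx = Ixx, iyy = Iyy, ixy = Ixy, scale = scale),
            class = "hessian_features")
}

#' Nematic alignment order parameter
#'
#' Treats the eigenvalue anisotropy `|lam_hi - lam_lo|` as the magnitude of a
#' nematic dipole directed along the principal eigenvector, averages the
#' orientation-doubled dipoles over a local window, and normalizes by the
#' summed magnitudes.  The returned field is `1 - |mean dipole|`, so ordered
#' regions (aligned cells and halos) are near 0 and disordered regions
#' (background) are near 1.  Windows with negligible total magnitude return
#' 1 (background by convention).
#'
#' @param f A [hessian_features()].
#' @param window Averaging window width in pixels.
#' @return Matrix in `[0, 1]`: high values mark unaligned background.
#' @export
alignment_order <- function(f, window) {
  stopifnot(inherits(f, "hessian_features"))
  if (window <= 0) stop("`window` must be positive", call. = FALSE)
  w <- abs(f$lam_hi - f$lam_lo)
  # orientation doubling: nematic director has period pi
  qx <- w * (f$ox^2 - f$oy^2)
  qy <- w * (2 * f$ox * f$oy)
  r <- max(1L, round(window / 2))
  box <- matrix(1, 2 * r + 1, 2 * r + 1)
  sw <- EBImage::filter2(w, box, boundary = "replicate")
  sqx <- EBImage::filter2(qx, box, boundary = "replicate")
  sqy <- EBImage::filter2(qy, box, boundary = "replicate")
  mag <- sqrt(sqx^2 + sqy^2)
  # windows with negligible total weight (featureless regions; also guards
  # against FFT round-off on constant images) fall back to order 1
  thr <- max(1e-12, 1e-6 * max(sw))
  ord <- ifelse(sw > thr, pmin(1, mag / pmax(sw, 1e-300)), 0)
  1 - ord
}

#' Project Hessian eigenvalues and intensity onto two principal components
#'
#' Standardizes the per-pixel 3-vectors (`lam_hi`, `lam_lo`, intensity) and
#' projects them onto the two leading principal axes of the pixel ensemble.
#' In bright-field bacteria images the three quantities are nearly coplanar,
#' so the discarded component carries only a small variance fraction
#' (reported in the result).
#'
#' @param lam_hi,lam_lo Eigenvalue fields from [hessian_features()].
#' @param intensity Raw intensity field, same shape.
#' @return List with fields `pc1`, `pc2` (matrices), `discarded_variance`
#'   (fraction), and the fitted `transform` (centers, scales, rotation) for
#'   applying the same projection to later frames via [apply_feature_pca()].
#' @export
feature_pca <- function(lam_hi, lam_lo, intensity) {
  stopifnot(all(dim(lam_hi) == dim(lam_lo)),
            all(dim(lam_hi) == dim(intensity)))
  X <- cbind(hi = as.vector(lam_hi), lo = as.vector(lam_lo),
             int = as.vector(intensity))
  sds <- apply(X, 2, sd)
  keep <- sds > 0
  if (!all(keep)) {
    warning("dropping zero-variance channel(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
    sds <- sds[keep]
  }
  if (ncol(X) < 2)
    stop("fewer than two channels with variance; cannot project",
         call. = FALSE)
  ctr <- colMeans(X)
  Xs <- sweep(sweep(X, 2, ctr), 2, sds, "/")
  sv <- svd(Xs, nu = 0)
  var_all <- sv$d^2
  discarded <- if (length(var_all) >= 3) var_all[3] / sum(var_all) else 0
  rot <- sv$v[, 1:2, drop = FALSE]
  scores <- Xs %*% rot
  dm <- dim(lam_hi)
  list(pc1 = matrix(scores[, 1], dm[1], dm[2]),
       pc2 = matrix(scores[, 2], dm[1], dm[2]),
       discarded_variance = discarded,
       transform = list(center = ctr, scale = sds, rotation = rot,
                        keep = keep))
}

#' Apply a fitted feature-PCA transform to new fields
#'
#' @param transform The `transform` element of a [feature_pca()] result.
#' @inheritParams feature_pca
#' @return List with `pc1` and `pc2` matrices.
#' @export
apply_feature_pca <- function(transform, lam_hi, lam_lo, intensity) {
  X <- cbind(as.vector(lam_hi), as.vector(lam_lo), as.vector(intensity))
  X <- X[, transform$keep, drop = FALSE]
  Xs <- sweep(sweep(X, 2, transform$center), 2, transform$scale, "/")
  scores <- Xs %*% transform$rotation
  dm <- dim(lam_hi)
  list(pc1 = matrix(scores[, 1], dm[1], dm[2]),
       pc2 = matrix(scores[, 2], dm[1], dm[2]))
}

#' Pixel class map
#'
#' Per-pixel probabilities of the three bright-field classes.  Probabilities
#' are non-negative and sum to one at every pixel.
#'
#' @param p_ridge,p_valley,p_background Probability matrices.
#' @return An object of class `pixel_class_map`.
#' @export
pixel_class_map <- function(p_ridge, p_valley, p_background) {
  s <- p_ridge + p_valley + p_background
  if (max(abs(s - 1)) > 1e-6)
    stop("class probabilities must sum to 1 per pixel", call. = FALSE)
  structure(list(p_ridge = p_ridge, p_valley = p_valley,
                 p_background = p_background),
            class = "pixel_class_map")
}

#' Classify pixels into ridge / valley / background with a 3-class EM
#'
#' Fits a 3-component full-covariance Gaussian mixture over the
#' (`pc1`, `pc2`) feature plane, where valley and ridge pixels form two
#' lobes and background occupies the junction between them, and returns
#' the posterior responsibilities as a [pixel_class_map()].  The alignment
#' `order` axis enters through the training stratification below: it is
#' what separates background from low-contrast cell areas.  Fitting uses deterministic
#' quantile stratification along the order axis: the mixture is fitted on
#' the confident strata only — high-order pixels (above `bg_quantile`) seed
#' and train the background component, low-order pixels (below
#' `cell_quantile`) are split by the median of `pc1` into the two feature
#' lobes — and the transition annulus between them is classified by the
#' E-step afterwards.  Pixels between cells and background otherwise pull
#' the mixture toward splitting the order axis into levels instead of
#' separating the two feature lobes.  Which pc1 lobe is the valley is
#' decided from the confident cores (the lobe with the larger mean
#' principal eigenvalue when `lam_hi` is given, the darker lobe when only
#' `intensity` is given) and the components retain their seeded identities
#' through the EM refinement.  Components are then labeled
#' by rule: background is the component with the highest mean order; of the
#' remaining two, valley is the lobe with the larger responsibility-weighted
#' mean principal Hessian eigenvalue (a dark line has strongly positive
#' curvature across it) and ridge the other.  When `lam_hi` is not supplied
#' the brighter lobe by weighted mean intensity is taken as the ridge.
#'
#' To bias toward under-segmented valleys (the direction the tracker is
#' robust to), `p_valley` is multiplied by `valley_shrink` before
#' renormalization.
#'
#' @param pc1,pc2 Principal-component fields from [feature_pca()].
#' @param order Alignment-order field from [alignment_order()].
#' @param intensity Raw intensity field, used for ridge/valley labeling
#'   when `lam_hi` is absent (ridge = brighter lobe).
#' @param lam_hi Principal Hessian eigenvalue field; the preferred labeling
#'   signal (valley = more positive lobe).
#' @param valley_shrink Factor in (0, 1] shrinking `p_valley` before
#'   renormalization (1 = no under-segmentation bias).
#' @param fit Optional previously fitted model (the `model` attribute of an
#'   earlier call); when supplied, only the E-step is run — used to classify
#'   later frames of a movie with the frame-1 classifier.
#' @param bg_quantile,cell_quantile Order-axis quantiles bounding the
#'   confident background / cell training strata.
#' @param use_prior Regularize covariances with [mclust::priorControl()]
#'   (guards against degenerate clusters on noise-free synthetic frames);
#'   disable for textbook maximum-likelihood EM.
#' @param subsample Fit the mixture on at most this many pixels (regular
#'   stride, deterministic); posteriors are still computed for all pixels.
#' @param max_iters,em_tol EM iteration control.
#' @return A [pixel_class_map()] with attributes `model` (reusable fit),
#'   `loglik` and `labels`.
#' @export
em_classify <- function(pc1, pc2, order, intensity = NULL, lam_hi = NULL,
                        valley_shrink = 0.8, fit = NULL,
                        bg_quantile = 0.8, cell_quantile = 0.3,
                        subsample = 20000L, max_iters = 200, em_tol = 1e-5,
                        use_prior = TRUE) {
  dm <- dim(pc1)
  X <- cbind(as.vector(pc1), as.vector(pc2), as.vector(order))
  m <- nrow(X)
  fit_cols <- 1:2  # the mixture lives in the (pc1, pc2) plane

  if (is.null(fit)) {
    idx <- if (m > subsample)
      round(seq(1, m, length.out = subsample)) else seq_len(m)
    Xs <- X[idx, , drop = FALSE]
    # confident strata along the order axis; the mid-order annulus is
    # excluded from fitting and classified by the final E-step
    q_hi <- quantile(Xs[, 3], bg_quantile, names = FALSE)
    q_lo <- quantile(Xs[, 3], cell_quantile, names = FALSE)
    conf_bg <- Xs[, 3] >= q_hi
    conf_cell <- Xs[, 3] <= q_lo
    if (q_hi <= q_lo) conf_cell <- !conf_bg  # degenerate order field
    # split the confident cell stratum into its two physical lobes: dark
    # line centers curve upward (positive principal eigenvalue), bright
    # halos downward; fall back to an intensity split, then to the pc1
    # median, when those fields are unavailable
    if (!is.null(lam_hi)) {
      lh_s <- as.vector(lam_hi)[idx]
      lobe_valley <- conf_cell & lh_s > 0
      lobe_ridge <- conf_cell & lh_s <= 0
    } else if (!is.null(intensity)) {
      iv_s <- as.vector(intensity)[idx]
      med_i <- median(iv_s[conf_cell])
      lobe_valley <- conf_cell & iv_s <= med_i
      lobe_ridge <- conf_cell & iv_s > med_i
    } else {
      med1 <- median(Xs[conf_cell, 1])
      lobe_valley <- conf_cell & Xs[, 1] <= med1
      lobe_ridge <- conf_cell & Xs[, 1] > med1
    }
    sel <- conf_bg | conf_cell
    Xf <- Xs[sel, , drop = FALSE]
    seed <- integer(nrow(Xf))
    seed[conf_bg[sel]] <- 3L
    seed[lobe_valley[sel]] <- 1L
    seed[lobe_ridge[sel]] <- 2L
    z0 <- matrix(0, nrow(Xf), 3)
    z0[cbind(seq_along(seed), seed)] <- 1
    mf <- mclust::meVVV(data = Xf[, fit_cols, drop = FALSE], z = z0,
                        prior = if (use_prior) mclust::priorControl(),
                        control = mclust::emControl(itmax = max_iters,
                                                    tol = em_tol))
    if (is.null(mf$parameters) || any(!is.finite(mf$loglik)))
      stop(sprintf("EM failed to converge (last log-likelihood %s)",
                   format(mf$loglik)), call. = FALSE)
    params <- mf$parameters
    loglik <- mf$loglik
  } else {
    params <- fit$parameters
    loglik <- NA_real_
  }

  es <- mclust::estepVVV(data = X[, fit_cols, drop = FALSE],
                         parameters = params)
  z <- es$z
  z[!is.finite(z)] <- 1 / 3

  if (is.null(fit)) {
    # components keep the identities they were seeded with (the EM refines
    # the clusters but does not permute them): 1 = valley, 2 = ridge,
    # 3 = background
    labels <- c(ridge = 2L, valley = 1L, background = 3L)
  } else {
    labels <- fit$labels
  }

  pr <- matrix(z[, labels["ridge"]], dm[1], dm[2])
  pv <- matrix(z[, labels["valley"]], dm[1], dm[2]) * valley_shrink
  pb <- matrix(z[, labels["background"]], dm[1], dm[2])
  tot <- pr + pv + pb
  out <- pixel_class_map(pr / tot, pv / tot, pb / tot)
  attr(out, "model") <- list(parameters = params, labels = labels)
  attr(out, "loglik") <- loglik
  attr(out, "labels") <- labels
  out
}

#' Synthesize the enhanced image potential from a class map
#'
#' The enhanced image is the weighted combination
#' `E = w_valley * p_valley + w_background * p_background + w_ridge *
#' p_ridge`, Gaussian-blurred.  The weight ordering
#' `w_valley < w_background < w_ridge` makes cell bodies the minima of the
#' potential, halos the maxima, and elevates the empty background so
#' contours cannot leak off the cells.
#'
#' @param m A [pixel_class_map()].
#' @param weights Named or ordered numeric of length 3:
#'   `c(valley, background, ridge)`.
#' @param sigma Final blur radius in pixels.
#' @return An [image_potential()].
#' @export
enhance_image <- function(m, weights = c(valley = 0, background = 0.7,
                                         ridge = 1), sigma = 3) {
  stopifnot(inherits(m, "pixel_class_map"))
  if (sigma <= 0) stop("`sigma` must be positive", call. = FALSE)
  w <- unname(weights)
  if (!(w[1] < w[2] && w[2] < w[3]))
    stop("weights must satisfy w_valley < w_background < w_ridge",
         call. = FALSE)
  E <- w[1] * m$p_valley + w[2] * m$p_background + w[3] * m$p_ridge
  image_potential(gaussian_blur(E, sigma), sigma = sigma)
}

#' Write a class map as a false-color PNG (red = ridge, green = valley,
#' blue = background)
#'
#' @param m A [pixel_class_map()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_class_map_png <- function(m, path) {
  arr <- array(0, dim = c(dim(m$p_ridge), 3))
  arr[, , 1] <- m$p_ridge
  arr[, , 2] <- m$p_valley
  arr[, , 3] <- m$p_background
  png::writePNG(arr, path)
  invisible(path)
}
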