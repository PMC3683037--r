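# Hessian features, alignment order, feature PCA, EM classification and
# enhanced-image synthesis

test_that("hessian features are exact on quadratic images", {
  img <- outer(0:49, 0:49, function(y, x) x^2 / 2)
  hf <- hessian_features(img, 1.5)
  interior <- 15:35
  expect_lt(max(abs(hf$lam_hi[interior, interior] - 1)), 1e-6)
  expect_lt(max(abs(hf$lam_lo[interior, interior])), 1e-6)
  # orientation of the principal eigenvector is along x
  expect_gt(min(abs(hf$ox[interior, interior])), 1 - 1e-6)
})

test_that("hessian eigen-decomposition reconstructs the Hessian", {
  withr::with_seed(8, {
    img <- gaussian_blur_probe(matrix(runif(48 * 48), 48), 1)
    hf <- hessian_features(img, 2)
    # reconstruct H = l1 v1 v1' + l2 v2 v2' at every pixel
    v2x <- -hf$oy; v2y <- hf$ox
    hxx <- hf$lam_hi * hf$ox^2 + hf$lam_lo * v2x^2
    hyy <- hf$lam_hi * hf$oy^2 + hf$lam_lo * v2y^2
    hxy <- hf$lam_hi * hf$ox * hf$oy + hf$lam_lo * v2x * v2y
    expect_lt(max(abs(hxx - hf$ixx)), 1e-6)
    expect_lt(max(abs(hyy - hf$iyy)), 1e-6)
    expect_lt(max(abs(hxy - hf$ixy)), 1e-6)
  })
})

test_that("hessian features are invariant to an additive constant and
           equivariant under 90-degree rotation", {
  withr::with_seed(12, {
    img <- gaussian_blur_probe(matrix(runif(40 * 40), 40), 1.5)
    hf1 <- hessian_features(img, 1.5)
    hf2 <- hessian_features(img + 0.37, 1.5)
    expect_equal(hf1$lam_hi, hf2$lam_hi, tolerance = 1e-10)
    # rotating the image by 90 degrees (exact on the grid) rotates the
    # eigenvalue fields identically
    rot <- t(img)[, rev(seq_len(ncol(img)))]  # counter-clockwise
    hfr <- hessian_features(rot, 1.5)
    lam_rot <- t(hf1$lam_hi)[, rev(seq_len(ncol(img)))]
    interior <- 8:32
    expect_equal(hfr$lam_hi[interior, interior],
                 lam_rot[interior, interior], tolerance = 1e-8)
  })
})

test_that("alignment order separates stripes from noise and degenerate
           fields", {
  stripes <- outer(0:63, 0:63, function(y, x) sin(y / 3))
  o1 <- alignment_order(hessian_features(stripes, 1.5), 8)
  expect_lt(median(o1[20:44, 20:44]), 0.1)

  withr::with_seed(4, {
    noise <- matrix(rnorm(64 * 64), 64)
    o2 <- alignment_order(hessian_features(noise, 1), 10)
    expect_gt(median(o2[20:44, 20:44]), 0.6)
  })

  flat <- matrix(0.5, 32, 32)
  o3 <- alignment_order(hessian_features(flat, 1.5), 8)
  expect_equal(max(abs(o3 - 1)), 0)
})

test_that("alignment order rotates with the image", {
  stripes <- outer(0:63, 0:63, function(y, x) sin(y / 3))
  o1 <- alignment_order(hessian_features(stripes, 1.5), 8)
  rot <- t(stripes)[, rev(1:64)]
  o2 <- alignment_order(hessian_features(rot, 1.5), 8)
  o1r <- t(o1)[, rev(1:64)]
  interior <- 12:52
  expect_equal(o2[interior, interior], o1r[interior, interior],
               tolerance = 1e-6)
})

test_that("feature_pca projects planar data losslessly", {
  withr::with_seed(6, {
    # data exactly in a plane: intensity = linear combination of the
    # eigenvalue channels
    a <- matrix(rnorm(900), 30)
    b <- matrix(rnorm(900), 30)
    int <- 0.6 * a - 0.3 * b
    fp <- feature_pca(a, b, int)
    expect_lt(fp$discarded_variance, 1e-20)
    # reapplying the stored transform reproduces the scores
    again <- apply_feature_pca(fp$transform, a, b, int)
    expect_equal(again$pc1, fp$pc1, tolerance = 1e-10)
  })
})

test_that("feature_pca drops zero-variance channels with a warning", {
  a <- matrix(rnorm(100), 10)
  b <- matrix(rnorm(100), 10)
  flat <- matrix(1, 10, 10)
  expect_warning(fp <- feature_pca(a, b, flat), "zero-variance")
  expect_equal(fp$discarded_variance, 0)
})

test_that("em_classify separates well-separated clusters near perfectly", {
  withr::with_seed(5, {
    n <- 10000
    cl <- sample(1:3, n, TRUE)
    centers <- rbind(c(-1, 0, 0.2),   # lobe 1
                     c(1, 0, 0.3),    # lobe 2
                     c(0, 1, 0.9))    # background: highest order
    X <- centers[cl, ] + matrix(rnorm(3 * n, 0, 0.1), n)
    dm <- c(100, 100)
    pc1 <- matrix(X[, 1], dm[1]); pc2 <- matrix(X[, 2], dm[1])
    ord <- matrix(X[, 3], dm[1])
    inten <- matrix(ifelse(cl == 2, 0.9, ifelse(cl == 1, 0.1, 0.5)),
                    dm[1])
    map <- em_classify(pc1, pc2, ord, intensity = inten, valley_shrink = 1)
    pred <- apply(cbind(as.vector(map$p_ridge), as.vector(map$p_valley),
                        as.vector(map$p_background)), 1, which.max)
    truth <- ifelse(cl == 2, 1, ifelse(cl == 1, 2, 3))
    expect_gte(mean(pred == truth), 0.99)
    # probabilities form a simplex
    s <- map$p_ridge + map$p_valley + map$p_background
    expect_lt(max(abs(s - 1)), 1e-6)
    # permuting pixel order leaves the per-pixel map unchanged
    perm <- withr::with_seed(9, sample(n))
    map2 <- em_classify(matrix(X[perm, 1], dm[1]),
                        matrix(X[perm, 2], dm[1]),
                        matrix(X[perm, 3], dm[1]),
                        intensity = matrix(as.vector(inten)[perm], dm[1]),
                        valley_shrink = 1)
    expect_equal(as.vector(map2$p_valley),
                 as.vector(map$p_valley)[perm], tolerance = 1e-3)
  })
})

test_that("EM log-likelihood is non-decreasing across iterations", {
  withr::with_seed(15, {
    n <- 2000
    cl <- sample(1:3, n, TRUE)
    centers <- rbind(c(-1, 0, 0.2), c(1, 0, 0.3), c(0, 0.5, 0.9))
    X <- centers[cl, ] + matrix(rnorm(3 * n, 0, 0.25), n)
    lls <- vapply(1:8, function(it) {
      map <- em_classify(matrix(X[, 1], 40), matrix(X[, 2], 40),
                        matrix(X[, 3], 40), max_iters = it,
                        use_prior = FALSE)
      attr(map, "loglik")
    }, numeric(1))
    expect_true(all(diff(lls) >= -1e-6))
  })
})

test_that("valley under-segmentation is monotone in the shrink factor", {
  withr::with_seed(16, {
    n <- 2500
    cl <- sample(1:3, n, TRUE)
    centers <- rbind(c(-1, 0, 0.2), c(1, 0, 0.3), c(0, 1, 0.9))
    X <- centers[cl, ] + matrix(rnorm(3 * n, 0, 0.15), n)
    pc1 <- matrix(X[, 1], 50); pc2 <- matrix(X[, 2], 50)
    ord <- matrix(X[, 3], 50)
    inten <- matrix(ifelse(cl == 2, 0.9, 0.2), 50)
    m1 <- em_classify(pc1, pc2, ord, intensity = inten, valley_shrink = 1)
    m2 <- em_classify(pc1, pc2, ord, intensity = inten,
                      valley_shrink = 0.7)
    expect_true(all(m2$p_valley <= m1$p_valley + 1e-9))
  })
})

test_that("classifier fitted on one frame reuses on another", {
  withr::with_seed(17, {
    mkframe <- function() {
      n <- 1600
      cl <- sample(1:3, n, TRUE)
      centers <- rbind(c(-1, 0, 0.2), c(1, 0, 0.3), c(0, 1, 0.9))
      X <- centers[cl, ] + matrix(rnorm(3 * n, 0, 0.1), n)
      list(pc1 = matrix(X[, 1], 40), pc2 = matrix(X[, 2], 40),
           ord = matrix(X[, 3], 40),
           inten = matrix(ifelse(cl == 2, 0.9, 0.2), 40), cl = cl)
    }
    f1 <- mkframe(); f2 <- mkframe()
    m1 <- em_classify(f1$pc1, f1$pc2, f1$ord, intensity = f1$inten)
    m2 <- em_classify(f2$pc1, f2$pc2, f2$ord, fit = attr(m1, "model"))
    pred <- apply(cbind(as.vector(m2$p_ridge), as.vector(m2$p_valley),
                        as.vector(m2$p_background)), 1, which.max)
    truth <- ifelse(f2$cl == 2, 1, ifelse(f2$cl == 1, 2, 3))
    expect_gte(mean(pred == truth), 0.95)
  })
})

test_that("enhanced image orders valley < background < ridge", {
  pv <- matrix(0, 20, 40); pv[, 1:20] <- 1
  pr <- matrix(0, 20, 40); pr[, 21:40] <- 1
  pb <- 1 - pv - pr
  m <- pixel_class_map(pr, pv, pb)
  pot <- enhance_image(m, c(valley = 0, background = 0.7, ridge = 1),
                       sigma = 2)
  # force near the boundary band points from the ridge side to the valley
  f <- image_force(pot, cbind(c(19, 21), c(10, 10)))
  expect_lt(f[1, 1], 0)
  expect_lt(f[2, 1], 0)
  # pure-valley map: constant potential, zero force
  all_v <- pixel_class_map(matrix(0, 10, 10), matrix(1, 10, 10),
                           matrix(0, 10, 10))
  pot2 <- enhance_image(all_v, sigma = 1)
  expect_lt(max(sqrt(pot2$gx^2 + pot2$gy^2)), 1e-12)
  # weight ordering is enforced
  expect_error(enhance_image(m, c(0.7, 0, 1), 2), "w_valley")
})

test_that("pixel_class_map validates the simplex constraint", {
  expect_error(pixel_class_map(matrix(0.5, 2, 2), matrix(0.5, 2, 2),
                               matrix(0.5, 2, 2)), "sum to 1")
})
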