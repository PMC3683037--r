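# per-frame relaxation, Sylvester membrane solves and block consistency

test_that("sylvester_solve matches a Kronecker-product oracle", {
  withr::with_seed(21, {
    for (rep in 1:10) {
      n <- sample(3:8, 1); T_ <- sample(2:6, 1)
      P <- matrix(rnorm(n * n), n) + diag(n) * 5
      B <- matrix(rnorm(T_ * T_), T_) * 0.3
      C <- matrix(rnorm(n * T_), n)
      X <- sylvester_solve(P, B, C)
      # independent route: vec(PX + XB) = (I (x) P + B' (x) I) vec(X)
      Xk <- matrix(solve(diag(T_) %x% P + t(B) %x% diag(n),
                         as.vector(C)), n)
      expect_equal(X, Xk, tolerance = 1e-8)
    }
  })
})

test_that("sylvester solve reports shared-eigenvalue degeneracy", {
  P <- diag(c(1, 2))
  B <- diag(c(-1, -3))   # P and -B share eigenvalue 1
  expect_error(sylvester_solve(P, B, matrix(1, 2, 2)), "gamma")
})

test_that("contours relax into a quadratic bowl", {
  pot <- bowl_potential(cx = 30, cy = 25)
  c1 <- contour(cbind(c(20, 22, 24), c(20, 20, 20)))
  op <- build_internal_operator(3, 0, 1, "open")
  cfg <- solver_config(max_iters = 2000, tol = 1e-5)
  out <- relax_frame(list(c1), pot, op, cfg)[[1]]
  expect_lt(max(abs(colMeans(out$points) - c(30, 25))), 0.05)
})

test_that("large gamma freezes the contour in one iteration", {
  pot <- bowl_potential()
  c1 <- contour(cbind(c(20, 22, 24), c(20, 21, 20)))
  cfg <- solver_config(gamma = 1e9, max_iters = 1)
  op <- build_internal_operator(3, 0, 1, "open")
  out <- relax_frame(list(c1), pot, op, cfg)[[1]]
  expect_lt(max(abs(out$points - c1$points)), 1e-6)
})

test_that("repulsion resolves two contours straddling merged wells", {
  # wells closer than twice their width merge into a single central
  # minimum; without repulsion both contours collapse into it, with
  # repulsion the two true wells are resolved
  dw <- double_well_potential(sep = 9, sigma = 5)
  mid <- colMeans(dw$wells)
  mk <- function(dx, id) contour(cbind(mid[1] + dx + c(-1, 0, 1),
                                       rep(mid[2], 3)), object_id = id)
  op <- build_internal_operator(3, 0, 1, "open")
  cfg <- solver_config(max_iters = 2000, tol = 1e-4)
  out0 <- relax_frame(list(mk(-1.5, "a"), mk(0.5, "b")), dw$potential, op,
                      cfg)
  gap0 <- sqrt(sum((colMeans(out0[[1]]$points) -
                      colMeans(out0[[2]]$points))^2))
  expect_lt(gap0, 2)
  rp <- repulsion_params(r0 = 10, epsilon = 0.5)
  out1 <- relax_frame(list(mk(-1.5, "a"), mk(0.5, "b")), dw$potential, op,
                      cfg, repulsion = rp)
  ca <- colMeans(out1[[1]]$points); cb <- colMeans(out1[[2]]$points)
  expect_gt(abs(ca[1] - cb[1]), 5)
  expect_lt(ca[1], mid[1]); expect_gt(cb[1], mid[1])
})

test_that("non-finite forces abort with object and iteration context", {
  P <- matrix(0, 32, 32); P[5, 5] <- NA
  expect_error(image_potential(P), "non-finite")
})

test_that("membrane block with pinned temporal ends interpolates linearly", {
  # zero image force, temporal_beta = 0: discrete harmonic in time
  flat <- image_potential(matrix(0, 64, 64))
  p0 <- cbind(c(10, 12, 14), c(10, 10, 10))
  pT <- p0 + 20
  c1 <- contour(p0, object_id = "a")
  T_ <- 6
  blk <- membrane_block(list(c1), 1:T_)
  blk$X[[1]][, , T_] <- pT
  op <- build_internal_operator(3, 0, 0, "open")  # no spatial elasticity
  cfg <- solver_config(max_iters = 4000, tol = 1e-7, temporal_alpha = 0.5,
                       temporal_beta = 0, redistribute_every = 0)
  pin <- c(TRUE, rep(FALSE, T_ - 2), TRUE)
  sol <- solve_membrane_block(blk, rep(list(flat), T_), op, cfg, pin = pin)
  for (t in 2:(T_ - 1)) {
    expected <- p0 + (pT - p0) * (t - 1) / (T_ - 1)
    expect_equal(sol$X[[1]][, , t], expected, tolerance = 1e-3,
                 ignore_attr = TRUE)
  }
})

test_that("single-frame blocks degenerate to per-frame relaxation", {
  pot <- bowl_potential()
  c1 <- contour(cbind(c(20, 22, 24), c(18, 18, 18)))
  op <- build_internal_operator(3, 0, 1, "open")
  cfg <- solver_config(max_iters = 500, tol = 1e-5)
  blk <- membrane_block(list(c1), 1L)
  sol <- solve_membrane_block(blk, list(pot), op, cfg)
  ref <- relax_frame(list(c1), pot, op, cfg)[[1]]
  expect_equal(sol$X[[1]][, , 1], ref$points, tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("a stationary object converges to identical time slices", {
  pot <- bowl_potential(cx = 30, cy = 25)
  c1 <- contour(cbind(c(28, 30, 32), c(25, 25, 25)))
  op <- build_internal_operator(3, 0, 1, "open")
  cfg <- solver_config(max_iters = 4000, tol = 1e-4, temporal_alpha = 0.1)
  blk <- membrane_block(list(c1), 1:5)
  withr::with_seed(3, {
    for (t in 1:5)
      blk$X[[1]][, , t] <- c1$points + matrix(rnorm(6, 0, 0.5), 3)
  })
  sol <- solve_membrane_block(blk, rep(list(pot), 5), op, cfg)
  resid <- attr(sol, "residual")
  expect_lte(resid, 10 * cfg$tol)
  spread <- max(abs(sol$X[[1]][, , 1] - sol$X[[1]][, , 5]))
  expect_lt(spread, 5 * cfg$tol)
  # per-frame oracle: same contour relaxed frame-by-frame
  ref <- relax_frame(list(c1), pot, op, cfg)[[1]]
  expect_equal(sol$X[[1]][, , 3], ref$points, tolerance = 0.05,
               ignore_attr = TRUE)
})

test_that("membrane equals per-frame relaxation as temporal stiffness
           vanishes", {
  pot <- bowl_potential(cx = 35, cy = 30)
  c1 <- contour(cbind(c(25, 27, 29), c(22, 22, 22)))
  op <- build_internal_operator(3, 0, 1, "open")
  cfg <- solver_config(max_iters = 3000, tol = 1e-5,
                       temporal_alpha = 1e-9, temporal_beta = 1e-9)
  blk <- membrane_block(list(c1), 1:4)
  sol <- solve_membrane_block(blk, rep(list(pot), 4), op, cfg)
  ref <- relax_frame(list(c1), pot, op, cfg)[[1]]
  for (t in 1:4)
    expect_equal(sol$X[[1]][, , t], ref$points, tolerance = 5 * cfg$tol,
                 ignore_attr = TRUE)
})

test_that("iteration residual is non-increasing on a convex potential", {
  pot <- bowl_potential()
  c1 <- contour(cbind(c(10, 12, 14), c(12, 12, 12)))
  op <- build_internal_operator(3, 0, 1, "open")
  blk0 <- membrane_block(list(c1), 1:4)
  resids <- vapply(seq(5, 50, by = 5), function(mi) {
    cfg <- solver_config(max_iters = mi, tol = 1e-12,
                         redistribute_every = 0)
    sol <- solve_membrane_block(blk0, rep(list(pot), 4), op, cfg)
    attr(sol, "residual")
  }, numeric(1))
  expect_true(all(diff(resids) <= 1e-9))
})

test_that("membrane tracking follows constant-velocity motion", {
  # moving Gaussian well, clean analytic potential
  n_frames <- 12
  v <- c(1.5, 0.8)
  make_pot <- function(f) {
    cx <- 15 + v[1] * (f - 1); cy <- 15 + v[2] * (f - 1)
    P <- outer(0:63, 0:63, function(y, x)
      -3 * exp(-((x - cx)^2 + (y - cy)^2) / 18))
    image_potential(P)
  }
  init <- list(contour(cbind(c(13, 15, 17), c(15, 15, 15)),
                       object_id = "m1"))
  op <- build_internal_operator(3, 0, 1, "open")
  cfg <- solver_config(max_iters = 400, tol = 1e-3)
  tr <- membrane_track(n_frames, make_pot, init, op, cfg,
                       img_dim = c(64, 64))
  cen <- track_centroids(tr)
  errs <- vapply(seq_len(n_frames), function(f) {
    truth <- c(15, 15) + v * (f - 1)
    sqrt(sum((cen[1, , f] - truth)^2))
  }, numeric(1))
  expect_lt(sqrt(mean(errs^2)), 0.5)
})

test_that("overlapping block frames agree between consecutive solves", {
  # stitching: pinned overlap makes consecutive blocks consistent
  n_frames <- 9
  make_pot <- function(f) bowl_potential(cx = 20 + f, cy = 20)
  init <- list(contour(cbind(c(18, 20, 22), c(20, 20, 20)),
                       object_id = "s1"))
  op <- build_internal_operator(3, 0, 1, "open")
  cfg <- solver_config(max_iters = 300, tol = 1e-3, block_size = 4,
                       block_overlap = 2)
  tr <- membrane_track(n_frames, make_pot, init, op, cfg,
                       img_dim = c(64, 64))
  # all frames tracked exactly once, no NA
  expect_true(all(is.finite(tr$points[[1]])))
  expect_equal(dim(tr$points[[1]])[3], n_frames)
})

test_that("zero frames give empty trajectories without error", {
  op <- build_internal_operator(3, 0, 1, "open")
  tr <- membrane_track(0L, NULL, list(), op, solver_config())
  expect_s3_class(tr, "ram_tracks")
  expect_equal(tr$n_frames, 0L)
  expect_equal(nrow(tidy(tr)), 0L)
})

test_that("objects leaving the field are retired as exited", {
  # well drifts off the image edge; contour follows and exits
  n_frames <- 25
  make_pot <- function(f) {
    cx <- 50 + 3 * (f - 1)
    P <- outer(0:63, 0:63, function(y, x)
      -3 * exp(-((x - cx)^2 + (y - 32)^2) / 18))
    image_potential(P)
  }
  init <- list(contour(cbind(c(48, 50, 52), c(32, 32, 32)),
                       object_id = "e1"))
  op <- build_internal_operator(3, 0, 1, "open")
  cfg <- solver_config(max_iters = 300, tol = 1e-3)
  tr <- membrane_track(n_frames, make_pot, init, op, cfg,
                       img_dim = c(64, 64))
  expect_false(is.na(tr$exited_frame[1]))
  f_exit <- tr$exited_frame[1]
  if (f_exit < n_frames)
    expect_true(all(is.na(tr$points[[1]][, , (f_exit + 1):n_frames])))
})
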