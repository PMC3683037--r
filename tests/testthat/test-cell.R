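# cell pipeline: skeleton initialization, shrink-and-regrow placement,
# tangential speed and reversal statistics

# class map with one or more straight synthetic rods (no imaging chain)
rod_classmap <- function(centers, angles, length = 40, width = 6,
                         size = 120) {
  px <- rep(0:(size - 1), each = size)
  py <- rep(0:(size - 1), times = size)
  D <- matrix(Inf, size, size)
  for (i in seq_along(angles)) {
    u <- c(cos(angles[i]), sin(angles[i]))
    a <- centers[i, ] - length / 2 * u
    b <- centers[i, ] + length / 2 * u
    d <- ramtrack:::point_segment_dist(px, py, a, b)
    D2 <- matrix(Inf, size, size); D2[cbind(py + 1, px + 1)] <- d
    D <- pmin(D, D2)
  }
  pv <- ifelse(D <= width / 2, 0.96, 0.02)
  pr <- ifelse(D > width / 2 & D < width, 0.9, 0.02)
  pb <- 1 - pv - pr
  pixel_class_map(pr, pv, pb)
}

test_that("init_cells fits one contour per straight rod", {
  cm <- rod_classmap(rbind(c(60, 60)), angles = 0.5)
  cfg <- cell_track_config(cell_width_px = 6)
  ic <- init_cells(cm, cfg)
  expect_length(ic, 1)
  # centerline RMSD against the true rod axis
  u <- c(cos(0.5), sin(0.5))
  a <- c(60, 60) - 20 * u; b <- c(60, 60) + 20 * u
  d <- ramtrack:::point_segment_dist(ic[[1]]$points[, 1],
                                     ic[[1]]$points[, 2], a, b)
  expect_lt(sqrt(mean(d^2)), 1)
})

test_that("init_cells keeps two parallel rods apart", {
  cm <- rod_classmap(rbind(c(55, 45), c(55, 65)), angles = c(0, 0),
                     width = 6)
  cfg <- cell_track_config(cell_width_px = 6)
  ic <- init_cells(cm, cfg)
  expect_length(ic, 2)
  c1 <- colMeans(ic[[1]]$points); c2 <- colMeans(ic[[2]]$points)
  expect_gt(abs(c1[2] - c2[2]), 10)
})

test_that("init_cells errors on an empty class map", {
  empty <- pixel_class_map(matrix(0, 30, 30), matrix(0, 30, 30),
                           matrix(1, 30, 30))
  cfg <- cell_track_config(cell_width_px = 6)
  expect_error(init_cells(empty, cfg), "no valley pixels")
})

test_that("thinning reduces rods to connected single-pixel paths", {
  px <- rep(1:60, each = 60); py <- rep(1:60, times = 60)
  d <- ramtrack:::point_segment_dist(px, py, c(15, 15), c(45, 40))
  m <- matrix(FALSE, 60, 60); m[cbind(py, px)] <- d <= 4
  s <- ramtrack:::thin_mask(m)
  expect_equal(max(EBImage::bwlabel(s)), 1)
  # single-pixel wide: no 2x2 block fully set
  blocks <- s[-1, -1] & s[-1, -60] & s[-60, -1] & s[-60, -60]
  expect_false(any(blocks))
})

test_that("shrink-and-regrow restores length in an open channel", {
  # straight valley potential: deep channel along y = 40
  P <- outer(0:79, 0:79, function(y, x) 0.7 - exp(-(y - 40)^2 / 8))
  pot <- image_potential(gaussian_blur_probe(P, 1))
  cfg <- cell_track_config(cell_width_px = 6, epsilon = 1)
  c1 <- contour(cbind(seq(20, 60, length.out = 25), rep(40, 25)),
                object_id = "c1")
  c1$target_length <- 40
  out <- shrink_regrow_step(list(c1), pot, cfg)
  L <- polyline_length(out[[1]]$points)
  expect_gt(L, 0.95 * 40)
  expect_lt(L, 1.05 * 40)
  # position unchanged: still centered on the channel
  expect_lt(max(abs(out[[1]]$points[, 2] - 40)), 0.5)
  expect_false(attr(out, "stunted")[1])
})

test_that("shrink_fraction = 1 reduces to plain relaxation", {
  P <- outer(0:79, 0:79, function(y, x) 0.7 - exp(-(y - 40)^2 / 8))
  pot <- image_potential(gaussian_blur_probe(P, 1))
  cfg <- cell_track_config(cell_width_px = 6, shrink_fraction = 1,
                           epsilon = 1)
  c1 <- contour(cbind(seq(25, 55, length.out = 25), rep(41.5, 25)),
                object_id = "c1")
  out <- shrink_regrow_step(list(c1), pot, cfg)
  expect_lt(max(abs(out[[1]]$points[, 2] - 40)), 0.5)
})

test_that("shrink-and-regrow frees a contour laid across a ridge", {
  # two parallel valleys with a ridge between them; contour initialized
  # crossing the ridge ends up entirely inside one valley
  tc <- two_channel_potential(size = 90, half_gap = 7)
  cfg <- cell_track_config(cell_width_px = 6, epsilon = 1,
                           solver = solver_config(max_iters = 400))
  withr::with_seed(33, {
    for (rep in 1:5) {
      # most of the contour lies in the right valley; the top quarter
      # leaks across the ridge into the left valley (the marginally
      # stable crossing configuration)
      n_cross <- 7
      ys <- seq(25, 60, length.out = 25) + rnorm(1, 0, 0.5)
      xs <- c(seq(tc$x_valleys[1], tc$x_valleys[2],
                  length.out = n_cross + 1)[seq_len(n_cross)],
              rep(tc$x_valleys[2], 25 - n_cross)) + rnorm(1, 0, 0.3)
      c1 <- contour(cbind(xs, rev(ys)), object_id = "r")
      c1$target_length <- polyline_length(c1$points)
      out <- shrink_regrow_step(list(c1), tc$potential, cfg)
      final_x <- out[[1]]$points[, 1]
      # the faulty crossing is eliminated: every point on one side
      expect_true(all(final_x < tc$x_ridge) || all(final_x > tc$x_ridge))
    }
  })
})

test_that("tangential speed recovers constant gliding and reversals", {
  # synthetic trajectory: straight 25-point contour gliding along +x
  mk_tracks <- function(disp) {
    n <- 25
    T_ <- length(disp) + 1
    a <- array(NA_real_, dim = c(n, 2, T_))
    pos <- 0
    for (f in 1:T_) {
      if (f > 1) pos <- pos + disp[f - 1]
      a[, , f] <- cbind(seq(pos, pos + 36, length.out = n), rep(30, n))
    }
    structure(list(object_ids = "c1", n_frames = T_, n_points = n,
                   points = list(a), target_length = 36,
                   jumped = matrix(FALSE, 1, T_),
                   lost = matrix(FALSE, 1, T_),
                   stunted = matrix(FALSE, 1, T_),
                   exited_frame = NA_integer_,
                   diagnostics = tibble::tibble(),
                   cfg = solver_config()),
              class = c("cell_tracks", "ram_tracks"))
  }
  cfg <- cell_track_config(cell_width_px = 8, um_per_px = 0.08,
                           frame_interval = 5, speed_smooth_sigma = 30)
  # constant velocity: constant speed, no reversals
  tr <- mk_tracks(rep(0.5, 40))
  sp <- tangential_speed(tr, cfg)
  expect_equal(sp$speed[10:35], rep(0.5 * 0.08 * 12, 26), tolerance = 1e-6)
  expect_equal(sum(sp$reversal), 0)

  # triangle wave with period 2p: reversals at every p (+- 1 frame)
  p <- 20
  disp <- rep(c(rep(0.8, p), rep(-0.8, p)), 3)
  tr2 <- mk_tracks(disp)
  sp2 <- tangential_speed(tr2, cfg)
  revs <- which(sp2$reversal)
  expected <- p + 1 + seq(0, 4 * p, by = p)
  expected <- expected[expected <= length(disp) + 1]
  expect_equal(length(revs), length(expected))
  expect_true(all(abs(revs - expected) <= 1))

  # sigma -> 0 returns the raw signed speed
  cfg0 <- cell_track_config(cell_width_px = 8, um_per_px = 0.08,
                            frame_interval = 5, speed_smooth_sigma = 0)
  sp0 <- tangential_speed(tr2, cfg0)
  expect_equal(sp0$speed, sp0$speed_raw)
})

test_that("speed histogram recovers an exponential mean", {
  withr::with_seed(41, {
    v <- rexp(10000, rate = 1 / 0.5)
    speeds <- tibble::tibble(object_id = "x", frame = seq_along(v),
                             speed_raw = v, speed = v, reversal = FALSE)
    sh <- speed_histogram(speeds, n_boot = 100)
    se <- 0.5 / sqrt(10000)
    expect_lt(abs(sh$mean - 0.5), 3 * se)
    expect_equal(sh$n, 10000)
    expect_equal(sum(sh$histogram$counts), 10000)
    expect_lt(sh$ci[1], sh$mean); expect_gt(sh$ci[2], sh$mean)
  })
  # all-zero speeds give mean 0
  z <- tibble::tibble(object_id = "x", frame = 1:10, speed_raw = 0,
                      speed = 0, reversal = FALSE)
  expect_equal(speed_histogram(z, n_boot = 10)$mean, 0)
})

test_that("a small dense cell movie tracks without identity swaps", {
  sp <- cell_movie_spec(n_objects = 8, image_size = 160, n_frames = 12,
                        seed = 4)
  mv <- simulate_cell_movie(sp)
  cfg <- cell_track_config(cell_width_px = sp$object_width_px)
  tr <- track_cells(mv$frames, cfg)
  expect_gte(length(tr$object_ids), 6)
  sc <- score_tracking(tr, mv$truth, match_radius = sp$object_length_px / 2)
  expect_equal(sc$n_swaps, 0)
  expect_gt(sc$fraction_tracked, 0.9)
  # per-frame apparent length within 5% of target off stunted frames
  for (k in seq_along(tr$object_ids)) {
    for (f in seq_len(tr$n_frames)) {
      if (tr$stunted[k, f]) next
      L <- ramtrack:::polyline_length(tr$points[[k]][, , f])
      expect_gt(L, 0.9 * tr$target_length[k])
    }
  }
})
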