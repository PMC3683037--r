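# fly pipeline: initialization, jump handling, Viterbi orientation,
# kinematics and contact statistics

make_fly_frame <- function(pos, theta, n_frames = 1, ...) {
  spec <- fly_movie_spec(n_objects = nrow(pos), n_frames = 1,
                         noise_sigma = 0, jump_rate = 0, ...)
  ramtrack:::render_fly_frame(pos, theta, spec)
}

test_that("init_flies finds the n largest blobs along their major axes", {
  withr::with_seed(31, {
    sp <- fly_movie_spec(n_objects = 5, n_frames = 1, noise_sigma = 0,
                         jump_rate = 0, seed = 31)
    mv <- simulate_fly_movie(sp)
    cfg <- fly_track_config(n_flies = 5, fly_length_px = 24,
                            fly_width_px = 9)
    init <- init_flies(mv$frames[[1]], cfg)
    expect_length(init, 5)
    tru <- mv$truth
    for (c in init) {
      cen <- colMeans(c$points)
      d <- sqrt((tru$x - cen[1])^2 + (tru$y - cen[2])^2)
      expect_lt(min(d), 1)
      # contour axis within a few degrees of the body axis
      o <- which.min(d)
      axis <- c$points[3, ] - c$points[1, ]
      ang <- atan2(axis[2], axis[1])
      dang <- abs(((ang - tru$angle[o]) + pi / 2) %% pi - pi / 2)
      expect_lt(dang, 0.15)
    }
  })
})

test_that("init_flies reports too few blobs and rejects blank frames", {
  cfg <- fly_track_config(n_flies = 3, fly_length_px = 24, fly_width_px = 9)
  one_fly <- make_fly_frame(matrix(c(100, 100), 1), 0.4)
  expect_error(init_flies(one_fly, cfg), "found 1")
  blank <- matrix(0.9, 128, 128)
  expect_error(init_flies(blank, cfg), "found 0|initialization")
})

test_that("detect_jump distinguishes deep wells from background", {
  frame <- make_fly_frame(matrix(c(80, 80), 1), 0)
  pot <- gaussian_potential(frame, 4.5, "dark_objects")
  bg <- median(pot$P)
  on_fly <- contour(cbind(c(72, 80, 88), c(80, 80, 80)))
  off_fly <- contour(cbind(c(150, 158, 166), c(150, 150, 150)))
  depth_on <- mean(ramtrack:::potential_at(pot, on_fly$points))
  thr <- (depth_on + bg) / 2
  expect_false(detect_jump(on_fly, pot, thr))
  expect_true(detect_jump(off_fly, pot, thr))
  expect_true(detect_jump(on_fly, pot, -Inf))
})

test_that("rescue_jumped relaxes a lost contour onto an unclaimed blob", {
  pos <- rbind(c(60, 60), c(160, 150))
  frame <- make_fly_frame(pos, c(0.3, 1.2), image_size = 220,
                          arena_radius_px = 100)
  cfg <- fly_track_config(n_flies = 2, fly_length_px = 24, fly_width_px = 9)
  pot0 <- gaussian_potential(frame, cfg$blur_sigma, "dark_objects")
  nrm <- max(sqrt(pot0$gx^2 + pot0$gy^2))
  pot <- image_potential(pot0$P / nrm, pot0$sigma)
  # contour stranded in the background; fly 1 is claimed by another contour
  claimed <- list(contour(cbind(c(54, 60, 66), c(60, 60, 60)),
                          object_id = "c1"))
  lost <- contour(cbind(c(100, 106, 112), c(100, 100, 100)),
                  target_length = 18, object_id = "lost")
  res <- rescue_jumped(lost, frame, pot, claimed, cfg)
  expect_false(is.null(res))
  expect_lt(sqrt(sum((colMeans(res$points) - pos[2, ])^2)), 2)
})

test_that("viterbi decoding matches exhaustive path search", {
  brute_force <- function(v, jumps, q, scale) {
    m <- length(v)
    states <- c(1, -1)
    best <- NULL; best_lp <- -Inf
    for (code in 0:(2^m - 1)) {
      path <- states[bitwAnd(bitwShiftR(code, 0:(m - 1)), 1L) + 1L]
      lp <- log(0.5) + plogis(path[1] * v[1] / scale, log.p = TRUE)
      if (m > 1) for (t in 2:m) {
        qt <- if (jumps[t]) 0.5 else q
        lp <- lp + log(ifelse(path[t] == path[t - 1], 1 - qt, qt)) +
          plogis(path[t] * v[t] / scale, log.p = TRUE)
      }
      if (lp > best_lp) { best_lp <- lp; best <- path }
    }
    best
  }
  withr::with_seed(23, {
    for (rep in 1:200) {
      m <- sample(1:12, 1)
      v <- rnorm(m, 0, 2)
      jumps <- runif(m) < 0.2
      q <- runif(1, 0.001, 0.2)
      got <- viterbi_head_correction(v, jumps, flip_prob = q,
                                     velocity_scale = 1)
      want <- brute_force(v, jumps, q, 1)
      expect_equal(got, as.integer(want))
    }
  })
})

test_that("viterbi handles uniform forward motion and jump flips", {
  v <- rep(2, 30)
  expect_equal(viterbi_head_correction(v), rep(1L, 30))
  # strong sign flip exactly at a jump frame: single state switch there
  v2 <- c(rep(2, 10), rep(-2, 10))
  jumps <- rep(FALSE, 20); jumps[11] <- TRUE
  path <- viterbi_head_correction(v2, jumps, flip_prob = 0.01)
  expect_equal(path, c(rep(1L, 10), rep(-1L, 10)))
  expect_equal(viterbi_head_correction(numeric(0)), integer(0))
})

test_that("velocity components follow the corrected heading", {
  # synthetic fly_tracks object moving along +x with heading +x
  mk_tracks <- function(sign_flip = FALSE) {
    pts <- lapply(1, function(k) {
      a <- array(NA_real_, dim = c(3, 2, 10))
      for (f in 1:10) {
        cx <- 10 + 2 * (f - 1)
        a[, , f] <- cbind(c(cx - 5, cx, cx + 5), c(20, 20, 20))
      }
      a
    })
    tr <- structure(list(
      object_ids = "f1", n_frames = 10L, n_points = 3L, points = pts,
      target_length = 10, jumped = matrix(FALSE, 1, 10),
      lost = matrix(FALSE, 1, 10), stunted = matrix(FALSE, 1, 10),
      exited_frame = NA_integer_,
      diagnostics = tibble::tibble(), cfg = solver_config()),
      class = c("fly_tracks", "ram_tracks"))
    tr$heading <- ramtrack:::raw_headings(tr)
    tr$orientation_sign <- matrix(if (sign_flip) -1L else 1L, 1, 10)
    tr
  }
  v <- velocity_components(mk_tracks())
  expect_equal(v$v_par[2:10], rep(2, 9), tolerance = 1e-9)
  expect_equal(v$v_perp[2:10], rep(0, 9), tolerance = 1e-9)
  # reversing the orientation sign negates the parallel component
  v2 <- velocity_components(mk_tracks(sign_flip = TRUE))
  expect_equal(v2$v_par[2:10], rep(-2, 9), tolerance = 1e-9)
})

test_that("relative positions land in the heading frame", {
  # fly a heads +x; fly b sits 5 px ahead: offset (0, +5)
  mk2 <- function() {
    mk <- function(cx, cy) {
      a <- array(NA_real_, dim = c(3, 2, 8))
      for (f in 1:8) a[, , f] <- cbind(c(cx - 5, cx, cx + 5), rep(cy, 3))
      a
    }
    tr <- structure(list(
      object_ids = c("a", "b"), n_frames = 8L, n_points = 3L,
      points = list(mk(50, 50), mk(55, 50)),
      target_length = c(10, 10), jumped = matrix(FALSE, 2, 8),
      lost = matrix(FALSE, 2, 8), stunted = matrix(FALSE, 2, 8),
      exited_frame = rep(NA_integer_, 2),
      diagnostics = tibble::tibble(), cfg = solver_config()),
      class = c("fly_tracks", "ram_tracks"))
    tr$heading <- ramtrack:::raw_headings(tr)
    tr$orientation_sign <- matrix(1L, 2, 8)
    tr
  }
  h <- relative_position_histogram(mk2(), "a", "b",
                                   breaks = seq(-10, 10, by = 2))
  expect_equal(sum(h$mass), 1)
  occupied <- which(h$mass > 0, arr.ind = TRUE)
  expect_equal(nrow(occupied), 1)
  mids <- seq(-9, 9, by = 2)
  expect_equal(mids[occupied[1, 1]], 5)   # parallel offset (rows = y)
  expect_equal(mids[occupied[1, 2]], -1)  # perpendicular ~ 0 (bin center)
})

test_that("contact counting follows the two-width rule", {
  tru <- dplyr::bind_rows(lapply(1:10, function(f)
    tibble::tibble(frame = f, object = 1:2,
                   x = c(0, 17), y = c(0, 0))))
  expect_equal(count_contacts(tru, fly_width_px = 9), 10L)
  tru2 <- dplyr::bind_rows(lapply(1:10, function(f)
    tibble::tibble(frame = f, object = 1:2, x = c(0, 30), y = c(0, 0))))
  expect_equal(count_contacts(tru2, fly_width_px = 9), 0L)
  tru3 <- tibble::tibble(frame = 1, object = 1:3,
                         x = c(0, 5, 10), y = c(0, 0, 0))
  expect_equal(count_contacts(tru3, fly_width_px = 9), 3L)
})

test_that("short fly movies track with correct identities", {
  sp <- fly_movie_spec(n_objects = 3, n_frames = 30, seed = 19,
                       image_size = 200, arena_radius_px = 60)
  mv <- simulate_fly_movie(sp)
  cfg <- fly_track_config(n_flies = 3, fly_length_px = 24, fly_width_px = 9,
                          blur_sigma = 5)
  tr <- track_flies(mv$frames, cfg)
  expect_length(tr$object_ids, 3)
  sc <- score_tracking(tr, mv$truth, match_radius = 24)
  expect_equal(sc$n_swaps, 0)
  expect_lt(sc$rmse, 3)  # small crowded arena: contact offsets dominate
  # orientation correction never changes positions, only sign metadata
  expect_true(all(tr$orientation_sign %in% c(-1L, 1L)))
  df <- tidy(tr)
  expect_true(all(c("heading_sign", "jumped") %in% names(df)))
  g <- glance(tr)
  expect_equal(g$n_objects, 3)
})
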