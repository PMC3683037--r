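# Semi-implicit relaxation of contours: per frame and as a spatio-temporal
# membrane solved block-wise through Sylvester equations.  Each iteration
# solves (A + gamma I) x_new = gamma x_old + f_ext(x_old) per spatial axis;
# for a block of frames the unknown is the n x T matrix of each coordinate
# over the block and the temporal elasticity enters as a right-multiplying
# operator, giving (A + gamma I) X + X B = gamma X_prev + F(X_prev).

#' Relaxation solver configuration
#'
#' @param gamma Step-size parameter (inverse time step) of the semi-implicit
#'   scheme; larger values take smaller steps.
#' @param max_iters Maximum relaxation iterations per solve.
#' @param tol Convergence threshold on the maximum point displacement per
#'   iteration, in pixels.
#' @param block_size Frames per time block of the membrane solve.
#' @param block_overlap Frames shared between consecutive blocks
#'   (`1 <= block_overlap < block_size`); overlap frames are pinned to the
#'   previous block's solution.
#' @param redistribute_every Apply uniform arc-length resampling every this
#'   many iterations (0 disables).
#' @param temporal_alpha,temporal_beta Stiffnesses of the temporal operator:
#'   `temporal_alpha` penalizes inter-frame displacement, `temporal_beta`
#'   penalizes accelerations (sharp turns of the trajectory).
#' @param predict Initial guess for new frames: `"hold"` copies the last
#'   solved slice forward; `"linear"` extrapolates linearly.
#' @return A list of class `solver_config`.
#' @export
solver_config <- function(gamma = 1, max_iters = 200, tol = 0.01,
                          block_size = 5, block_overlap = 1,
                          redistribute_every = 5,
                          temporal_alpha = 0.005, temporal_beta = 0.05,
                          predict = c("hold", "linear")) {
  predict <- match.arg(predict)
  if (gamma <= 0) stop("`gamma` must be positive", call. = FALSE)
  if (tol <= 0) stop("`tol` must be positive", call. = FALSE)
  if (block_size < 2) stop("`block_size` must be >= 2", call. = FALSE)
  if (block_overlap < 1 || block_overlap >= block_size)
    stop("`block_overlap` must satisfy 1 <= overlap < block_size",
         call. = FALSE)
  structure(list(gamma = gamma, max_iters = as.integer(max_iters), tol = tol,
                 block_size = as.integer(block_size),
                 block_overlap = as.integer(block_overlap),
                 redistribute_every = as.integer(redistribute_every),
                 temporal_alpha = temporal_alpha,
                 temporal_beta = temporal_beta,
                 predict = predict),
            class = "solver_config")
}

# assemble per-object external forces for one time slice.
# extra_force(k, pts, frame, iter, base) adds pipeline terms (tips, rescue)
# on top of the image + repulsion base force.
slice_forces <- function(points_list, potential, repulsion, prev_points_list,
                         extra_force, frame, iter, avg_tangential) {
  K <- length(points_list)
  # one batched interpolation for all objects in the slice
  ns <- vapply(points_list, nrow, integer(1))
  all_f <- image_force(potential, do.call(rbind, points_list))
  off <- c(0L, cumsum(ns))
  base <- lapply(seq_len(K), function(k)
    all_f[(off[k] + 1):off[k + 1], , drop = FALSE])
  if (!is.null(repulsion)) {
    rep_f <- repulsion_forces(points_list, repulsion, prev_points_list)
    for (k in seq_len(K)) base[[k]] <- base[[k]] + rep_f[[k]]
  }
  # tangential averaging smooths the image/repulsion relaxation only; it is
  # applied before the pipeline extra forces so that deliberately tangential
  # terms (tip growth) are not averaged away
  out <- base
  if (avg_tangential)
    for (k in seq_len(K))
      out[[k]] <- average_tangential_force(points_list[[k]], out[[k]])
  if (!is.null(extra_force)) {
    for (k in seq_len(K)) {
      ef <- extra_force(k, points_list[[k]], frame, iter, base[[k]])
      if (!is.null(ef)) out[[k]] <- out[[k]] + ef
    }
  }
  out
}

check_finite_forces <- function(forces, ids, iter) {
  for (k in seq_along(forces)) {
    if (!all(is.finite(forces[[k]])))
      stop(sprintf("non-finite force for object '%s' at iteration %d",
                   ids[k], iter), call. = FALSE)
  }
}

#' Relax contours against an image potential for a single frame
#'
#' Iterates the semi-implicit scheme
#' `(A + gamma I) x_new = gamma x_old + f_ext(x_old)` per spatial axis until
#' the largest point displacement falls below `tol` or `max_iters` is
#' reached.  The external force is the image force plus optional repulsion
#' between the supplied contours and any pipeline-specific extra force.
#'
#' @param contours List of [contour()] objects sharing `n` and topology.
#' @param potential An [image_potential()].
#' @param op An [build_internal_operator()] matching the contours.
#' @param cfg A [solver_config()].
#' @param repulsion Optional [repulsion_params()] coupling the contours.
#' @param extra_force Optional `function(k, pts, frame, iter, base_force)`
#'   returning an additional n x 2 force for object `k` (or `NULL`).
#' @param avg_tangential Apply [average_tangential_force()] each iteration.
#' @param frame Frame index passed through to `extra_force`.
#' @return The relaxed contours (same ids and order), with attributes
#'   `iterations` and `converged`.
#' @export
relax_frame <- function(contours, potential, op, cfg,
                        repulsion = NULL, extra_force = NULL,
                        avg_tangential = FALSE, frame = 1L) {
  stopifnot(inherits(cfg, "solver_config"), inherits(op, "internal_operator"))
  if (length(contours) == 0) return(contours)
  ids <- vapply(contours, function(c) as.character(c$object_id), character(1))
  X <- lapply(contours, function(c) c$points)
  S <- solve(op$matrix + cfg$gamma * diag(op$n))
  prev <- NULL
  iters <- 0L
  converged <- FALSE
  for (iter in seq_len(cfg$max_iters)) {
    iters <- iter
    f <- slice_forces(X, potential, repulsion, prev, extra_force,
                      frame, iter, avg_tangential)
    check_finite_forces(f, ids, iter)
    prev <- X
    disp <- 0
    for (k in seq_along(X)) {
      Xn <- S %*% (cfg$gamma * X[[k]] + f[[k]])
      disp <- max(disp, max(abs(Xn - X[[k]])))
      X[[k]] <- Xn
    }
    if (cfg$redistribute_every > 0 && iter %% cfg$redistribute_every == 0 &&
        op$topology == "open") {
      X <- lapply(X, resample_polyline, n = op$n)
    }
    if (disp < cfg$tol) { converged <- TRUE; break }
  }
  out <- lapply(seq_along(X), function(k) {
    c0 <- contours[[k]]; c0$points <- X[[k]]; c0
  })
  attr(out, "iterations") <- iters
  attr(out, "converged") <- converged
  out
}

#' Create a membrane block
#'
#' A membrane block stacks the contours of the tracked objects over a
#' contiguous frame range; it is the unknown of the block-wise Sylvester
#' relaxation.
#'
#' @param contours List of [contour()] objects (one per object, defining the
#'   initial slice geometry).
#' @param frames Integer vector of contiguous frame indices.
#' @param X Optional list (per object) of `n x 2 x T` arrays of initial
#'   positions; defaults to replicating each contour over the block.
#' @return An object of class `membrane_block`.
#' @export
membrane_block <- function(contours, frames, X = NULL) {
  T_ <- length(frames)
  if (is.null(X)) {
    X <- lapply(contours, function(c)
      array(c$points, dim = c(nrow(c$points), 2, T_)))
  }
  structure(list(contours = contours, frames = as.integer(frames), X = X),
            class = "membrane_block")
}

#' Solve one membrane block
#'
#' Relaxes the spatio-temporal membrane of every object over a block of
#' frames.  Each iteration evaluates the external forces per time slice at
#' the previous iterate and solves, per object and spatial axis, the
#' Sylvester system
#' `(A + gamma I) X + X B = gamma X_prev + F(X_prev)`
#' where `B` is the temporal operator (same banded structure as the spatial
#' one, transposed).  Control points move only within their own time slice.
#' Frames marked in `pin` are held fixed at their initial values (used to
#' condition a block on the previous block's solution); the solve then acts
#' on the free columns with the pinned columns folded into the right-hand
#' side.
#'
#' @param block A [membrane_block()].
#' @param potentials List of [image_potential()]s, one per block frame.
#' @param op An [build_internal_operator()] for the spatial axis.
#' @param cfg A [solver_config()]; `temporal_alpha`/`temporal_beta` set the
#'   temporal operator.
#' @param pin Logical vector over block frames; pinned slices do not move.
#' @param repulsion Optional [repulsion_params()].
#' @param extra_force As in [relax_frame()].
#' @param avg_tangential Apply tangential-force averaging per slice.
#' @return The solved `membrane_block`, with attributes `iterations`,
#'   `converged` and `residual` (max norm of `A X + X B - F` over free
#'   columns at the returned iterate).
#' @export
solve_membrane_block <- function(block, potentials, op, cfg,
                                 pin = NULL, repulsion = NULL,
                                 extra_force = NULL,
                                 avg_tangential = FALSE) {
  stopifnot(inherits(block, "membrane_block"), inherits(cfg, "solver_config"))
  T_ <- length(block$frames)
  K <- length(block$X)
  ids <- vapply(block$contours, function(c) as.character(c$object_id),
                character(1))
  if (is.null(pin)) pin <- rep(FALSE, T_)
  if (length(pin) != T_) stop("`pin` must match the block length",
                              call. = FALSE)
  n <- op$n
  # T_ == 1 degenerates to per-frame relaxation (temporal operator is NULL)
  B <- temporal_operator(T_, cfg$temporal_alpha, cfg$temporal_beta)
  free <- which(!pin)
  if (length(free) == 0) {
    attr(block, "iterations") <- 0L
    attr(block, "converged") <- TRUE
    attr(block, "residual") <- 0
    return(block)
  }
  P <- op$matrix + cfg$gamma * diag(n)
  if (is.null(B) || length(free) == 0) {
    fac <- sylvester_factor(P, NULL)
    Bff <- NULL; Bpf <- NULL
  } else {
    Bff <- B[free, free, drop = FALSE]
    fac <- sylvester_factor(P, Bff)
    pinned <- which(pin)
    Bpf <- if (length(pinned)) B[pinned, free, drop = FALSE] else NULL
  }

  X <- block$X  # list of n x 2 x T arrays
  prev_slices <- NULL
  iters <- 0L
  converged <- FALSE
  last_F <- vector("list", T_)

  # forces are needed only on free time slices (pinned columns never enter
  # the right-hand side or the residual)
  eval_forces <- function(Xcur, prev, iter) {
    Fs <- vector("list", T_)
    for (t in free) {
      pts_t <- lapply(Xcur, function(a) a[, , t, drop = FALSE][, , 1])
      prev_t <- if (is.null(prev)) NULL else
        lapply(prev, function(a) a[, , t, drop = FALSE][, , 1])
      f <- slice_forces(pts_t, potentials[[t]], repulsion, prev_t,
                        extra_force, block$frames[t], iter, avg_tangential)
      check_finite_forces(f, ids, iter)
      Fs[[t]] <- f
    }
    Fs
  }

  for (iter in seq_len(cfg$max_iters)) {
    iters <- iter
    Fs <- eval_forces(X, prev_slices, iter)
    last_F <- Fs
    prev_slices <- X
    disp <- 0
    for (k in seq_len(K)) {
      for (ax in 1:2) {
        Xk <- X[[k]][, ax, ]                      # n x T
        if (T_ == 1L) Xk <- matrix(Xk, ncol = 1)
        Fk <- vapply(seq_len(T_), function(t)
          if (is.null(Fs[[t]])) numeric(n) else Fs[[t]][[k]][, ax],
          numeric(n))                             # n x T (zeros if pinned)
        if (is.matrix(Fk) == FALSE) Fk <- matrix(Fk, nrow = n)
        R <- cfg$gamma * Xk + Fk
        Cf <- R[, free, drop = FALSE]
        if (!is.null(Bpf))
          Cf <- Cf - Xk[, pin, drop = FALSE] %*% Bpf
        Xf <- fac$solve(Cf)
        disp <- max(disp, max(abs(Xf - Xk[, free, drop = FALSE])))
        Xk[, free] <- Xf
        X[[k]][, ax, ] <- Xk
      }
    }
    if (cfg$redistribute_every > 0 && iter %% cfg$redistribute_every == 0 &&
        op$topology == "open") {
      for (k in seq_len(K)) for (t in free) {
        X[[k]][, , t] <- resample_polyline(X[[k]][, , t], n)
      }
    }
    if (disp < cfg$tol) { converged <- TRUE; break }
  }

  # fixed-point residual A X + X B - F on free columns, forces re-evaluated
  # at the returned iterate
  Fs <- eval_forces(X, prev_slices, iters + 1L)
  resid <- 0
  for (k in seq_len(K)) for (ax in 1:2) {
    Xk <- X[[k]][, ax, ]
    if (T_ == 1L) Xk <- matrix(Xk, ncol = 1)
    Fk <- vapply(seq_len(T_), function(t)
      if (is.null(Fs[[t]])) numeric(n) else Fs[[t]][[k]][, ax], numeric(n))
    if (is.matrix(Fk) == FALSE) Fk <- matrix(Fk, nrow = n)
    R <- op$matrix %*% Xk + (if (is.null(B)) 0 else Xk %*% B) - Fk
    resid <- max(resid, max(abs(R[, free, drop = FALSE])))
  }

  block$X <- X
  attr(block, "iterations") <- iters
  attr(block, "converged") <- converged
  attr(block, "residual") <- resid
  block
}
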