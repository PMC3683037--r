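# Sylvester solves P X + X B = C via eigendecomposition of the two (small)
# operators.  P = A + gamma I is n x n, B is T x T; both are dense and tiny
# (n <= ~25 control points, T <= ~7 frames), so diagonalizing once per block
# and reusing the factors across relaxation iterations is the efficient route.

#' Factor a Sylvester system for repeated solves
#'
#' Prepares a solver for `P X + X B = C` with fixed `P` (n x n) and `B`
#' (T x T).  The returned closure solves for `X` given any right-hand side
#' `C`, reusing the eigendecompositions.  Fails when `P` and `-B` share an
#' eigenvalue (the system is then singular); increasing the damping `gamma`
#' folded into `P` separates the spectra.
#'
#' @param P Left matrix (n x n).
#' @param B Right matrix (T x T), or `NULL` for the degenerate single-frame
#'   case (then the solve is just `P X = C`).
#' @return List with `solve(C)` and the eigenvalue grid `denom`.
#' @keywords internal
sylvester_factor <- function(P, B = NULL) {
  if (is.null(B)) {
    Pi <- solve(P)
    return(list(solve = function(C) Pi %*% C, denom = NULL))
  }
  eP <- eigen(P)
  eB <- eigen(B)
  U <- eP$vectors; Ui <- solve(U)
  V <- eB$vectors; Vi <- solve(V)
  denom <- outer(eP$values, eB$values, `+`)
  scale <- max(Mod(eP$values), Mod(eB$values), 1)
  if (min(Mod(denom)) < 1e-10 * scale)
    stop(paste("Sylvester solve is singular: the spatial and temporal",
               "operators share an eigenvalue; increase gamma"),
         call. = FALSE)
  list(
    solve = function(C) {
      Y <- (Ui %*% C %*% V) / denom
      X <- U %*% Y %*% Vi
      if (is.complex(X)) X <- Re(X)
      X
    },
    denom = denom
  )
}

#' Solve a Sylvester equation P X + X B = C
#'
#' One-shot convenience wrapper around [sylvester_factor()].
#'
#' @inheritParams sylvester_factor
#' @param C Right-hand side (n x T).
#' @return The solution matrix `X`.
#' @export
sylvester_solve <- function(P, B, C) {
  sylvester_factor(P, B)$solve(C)
}
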