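#' Find an equilibrium of the loop under constant inputs
#'
#' Solves the fixed-point equations (delays are irrelevant at equilibrium)
#' \deqn{\bar x_1 = S_1(c_{11}\bar x_1 - c_{12}\bar x_2 + b_1 \bar u_1), \quad
#'       \bar x_2 = S_2(c_{21}\bar x_1 - c_{22}\bar x_2 - b_2 \bar u_2)}
#' by a nested one-dimensional reduction: for each candidate `x1` the inner
#' GPe equation is solved by bisection (its residual is strictly monotone in
#' `x2`), and the outer STN residual is then bracketed on `[0, a1*M1]`. A
#' Newton polish brings the residual below `tol`. This is robust for any
#' non-negative couplings, including strong GPe self-inhibition.
#'
#' @param p A [loopParams()] object.
#' @param u1bar,u2bar Constant input levels.
#' @param tol Residual tolerance (default 1e-10).
#' @return Object of class `Equilibrium`: list with `x1`, `x2`, `residual`.
#' @export
findEquilibrium <- function(p, u1bar, u2bar = 2, tol = 1e-10) {
  stopifnot(inherits(p, "LoopParams"))
  M1a <- p$S1$a * p$S1$M
  M2a <- p$S2$a * p$S2$M

  innerX2 <- function(x1) {
    g <- function(x2) x2 - activation(p$S2, p$c21 * x1 - p$c22 * x2 - p$b2 * u2bar)
    # g(0) < 0, g(M2a) > 0 since 0 < S2 < M2a
    stats::uniroot(g, c(0, M2a), tol = 1e-13)$root
  }
  outer <- function(x1) x1 - activation(p$S1, p$c11 * x1 - p$c12 * innerX2(x1) + p$b1 * u1bar)
  x1 <- stats::uniroot(outer, c(0, M1a), tol = 1e-13)$root
  x2 <- innerX2(x1)

  resid <- function(x1, x2) {
    c(x1 - activation(p$S1, p$c11 * x1 - p$c12 * x2 + p$b1 * u1bar),
      x2 - activation(p$S2, p$c21 * x1 - p$c22 * x2 - p$b2 * u2bar))
  }
  # Newton polish on the 2-D residual
  for (it in 1:50) {
    r <- resid(x1, x2)
    if (max(abs(r)) < tol) break
    q1 <- p$c11 * x1 - p$c12 * x2 + p$b1 * u1bar
    q2 <- p$c21 * x1 - p$c22 * x2 - p$b2 * u2bar
    s1 <- activationSlope(p$S1, q1)
    s2 <- activationSlope(p$S2, q2)
    J <- matrix(c(1 - s1 * p$c11, s1 * p$c12,
                  -s2 * p$c21, 1 + s2 * p$c22), 2, 2, byrow = TRUE)
    step <- solve(J, r)
    x1 <- x1 - step[1]; x2 <- x2 - step[2]
  }
  r <- resid(x1, x2)
  if (max(abs(r)) >= tol)
    stop(sprintf("equilibrium solver did not converge: residual %.3e after Newton polish",
                 max(abs(r))))
  structure(list(x1 = x1, x2 = x2, residual = max(abs(r)),
                 u1bar = u1bar, u2bar = u2bar),
            class = "Equilibrium")
}

#' @export
print.Equilibrium <- function(x, ...) {
  cat(sprintf("<Equilibrium> x1 = %.6f, x2 = %.6f pulses/s (residual %.2e)\n",
              x$x1, x$x2, x$residual))
  invisible(x)
}
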