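#' Sigmoid activation parameters
#'
#' Parameters of the population activation function
#' \deqn{S(x) = \frac{M B}{B + e^{-4x/M}(M - B)},}
#' a logistic nonlinearity with maximum firing rate `M` (pulses/s), baseline
#' rate `B = S(0)` (pulses/s) and unit maximum slope. An optional output scale
#' `a` multiplies the whole curve (so the maximum slope becomes `a`), as used
#' when an activation is identified from data and rescaled.
#'
#' @param M Maximum firing rate (pulses/s), `M > B`.
#' @param B Baseline firing rate at zero drive (pulses/s), `0 < B < M`.
#' @param a Dimensionless output scale, `a > 0` (default 1).
#' @return An object of class `ActivationParams`.
#' @examples
#' p <- activationParams(M = 300, B = 17)
#' activation(p, 0)    # equals B
#' @export
activationParams <- function(M, B, a = 1) {
  stopifnot(is.numeric(M), is.numeric(B), is.numeric(a), length(M) == 1,
            length(B) == 1, length(a) == 1)
  if (!(B > 0 && B < M)) stop("activation requires 0 < B < M")
  if (!(a > 0)) stop("activation scale a must be positive")
  structure(list(M = M, B = B, a = a), class = "ActivationParams")
}

#' @export
print.ActivationParams <- function(x, ...) {
  cat(sprintf("<ActivationParams> M = %g, B = %g, scale a = %g (max slope %g)\n",
              x$M, x$B, x$a, x$a))
  invisible(x)
}

#' Evaluate a population activation function
#'
#' Overflow-safe evaluation of the sigmoid via its logistic form
#' `a * M * plogis(4 x / M - log((M - B) / B))`. Output lies strictly in
#' `(0, a*M)` and is strictly increasing in `x`.
#'
#' @param p An [activationParams()] object.
#' @param x Input drive (numeric vector).
#' @return Firing rate(s) in pulses/s.
#' @export
activation <- function(p, x) {
  stopifnot(inherits(p, "ActivationParams"))
  p$a * p$M * stats::plogis(4 * x / p$M - log((p$M - p$B) / p$B))
}

#' Derivative of a population activation function
#'
#' Closed-form derivative `a * 4 * s * (1 - s)` where `s` is the underlying
#' unit logistic; maximum value is `a`, attained where `S = a*M/2`.
#'
#' @inheritParams activation
#' @return Slope(s), dimensionless.
#' @export
activationSlope <- function(p, x) {
  stopifnot(inherits(p, "ActivationParams"))
  s <- stats::plogis(4 * x / p$M - log((p$M - p$B) / p$B))
  p$a * 4 * s * (1 - s)
}

#' Maximum slope of an activation function
#'
#' The supremum of the derivative, found numerically: a central
#' finite-difference derivative is scanned over a grid spanning the sigmoid's
#' dynamic range and the best cell is refined with [stats::optimize()]. For
#' the unit-scale sigmoid the result is 1 to within the search tolerance.
#'
#' @inheritParams activation
#' @return Maximum slope (dimensionless).
#' @export
activationMaxSlope <- function(p) {
  stopifnot(inherits(p, "ActivationParams"))
  h <- p$M * 1e-5
  fd <- function(x) (activation(p, x + h) - activation(p, x - h)) / (2 * h)
  grid <- seq(-2 * p$M, 2 * p$M, length.out = 801)
  i <- which.max(fd(grid))
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  stats::optimize(fd, c(lo, hi), maximum = TRUE, tol = 1e-10)$objective
}

#' Shift an activation function to vanish at zero
#'
#' Returns the function `f(y) = S(y + x0) - S(x0)`, the coordinate change used
#' when analyzing the loop about an equilibrium: the shifted activation
#' satisfies `f(0) = 0` while keeping monotonicity and maximum slope.
#'
#' @inheritParams activation
#' @param x0 Offset argument (the equilibrium drive), finite scalar.
#' @return A function of one argument.
#' @export
shiftActivation <- function(p, x0) {
  stopifnot(inherits(p, "ActivationParams"), is.finite(x0))
  force(p); force(x0)
  function(y) activation(p, y + x0) - activation(p, x0)
}
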