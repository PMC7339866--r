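#' Steady-state STN/GPe rate pairs
#'
#' Input-output data for identifying the GPe activation function and
#' self-coupling: each pair is a constant STN drive `u` and the resulting
#' GPe steady-state rate `x2`.
#'
#' @param u STN firing rates (pulses/s, `>= 0`).
#' @param x2 GPe steady-state rates (pulses/s, `>= 0`).
#' @return A `RatePairs` data frame.
#' @export
ratePairs <- function(u, x2) {
  stopifnot(length(u) == length(x2), all(u >= 0), all(x2 >= 0))
  if (length(unique(u)) < 4)
    stop("need at least 4 distinct drive values for a 3-parameter sigmoid fit")
  structure(data.frame(u = u, x2 = x2), class = c("RatePairs", "data.frame"))
}

#' Generate synthetic steady-state rate pairs
#'
#' Samples drives uniformly over `uRange`, computes the exact GPe steady
#' state under a known activation and self-coupling via [gpeSteadyState()],
#' and applies multiplicative Gaussian noise. Used to exercise and validate
#' the identification procedure.
#'
#' @param S2 True GPe [activationParams()] (scale included).
#' @param c22 True self-coupling.
#' @param n Number of pairs.
#' @param uRange Drive range (pulses/s) covering the sigmoid's dynamic range.
#' @param noiseSd Multiplicative noise standard deviation (e.g. 0.05).
#' @param seed Optional RNG seed.
#' @return A [ratePairs()] object.
#' @export
generateRatePairs <- function(S2, c22, n = 50,
                              uRange = c(0, 250), noiseSd = 0, seed = NULL) {
  stopifnot(inherits(S2, "ActivationParams"), n >= 4)
  if (!is.null(seed)) set.seed(seed)
  u <- sort(stats::runif(n, uRange[1], uRange[2]))
  x2 <- .gpeSteadyStateVec(S2, c22, u)
  if (noiseSd > 0) x2 <- pmax(0, x2 * (1 + stats::rnorm(n, 0, noiseSd)))
  ratePairs(u, x2)
}

#' Fit the GPe activation function from self-coupling-free rate pairs
#'
#' Implements the two-stage estimate: (i) a least-squares line through the
#' central 50% of the drive range gives the output scale `a` (the data's
#' near-linear slope); (ii) a unit-slope sigmoid of the standard form is
#' fitted to the rescaled data `x2 / a`; the returned activation is `a`
#' times that sigmoid. A final joint refinement of `(a, M, B)` by nonlinear
#' least squares (initialized at the two-stage estimate, `refine = TRUE`)
#' removes the bias of the chord-slope estimate of `a` so that noiseless
#' data are recovered exactly.
#'
#' @param pairs A [ratePairs()] generated with zero self-coupling.
#' @param refine Run the joint refinement (default `TRUE`).
#' @return List of class `ActivationFit`: `a` (scale), `params`
#'   ([activationParams()] with the fitted `M`, `B` and scale `a`), and the
#'   residual sum of squares `rss`.
#' @export
fitActivation <- function(pairs, refine = TRUE) {
  stopifnot(inherits(pairs, "RatePairs"))
  u <- pairs$u; x2 <- pairs$x2
  if (stats::sd(x2) < 1e-12) stop("degenerate data: constant GPe rate")
  qs <- stats::quantile(u, c(0.25, 0.75))
  mid <- u >= qs[1] & u <= qs[2]
  if (sum(mid) < 2) mid <- rep(TRUE, length(u))
  a0 <- unname(stats::coef(stats::lm(x2[mid] ~ u[mid]))[2])
  if (!is.finite(a0) || a0 <= 0)
    stop("degenerate data: central slope is not positive")

  xs <- x2 / a0
  M0 <- max(xs) * 1.05
  B0 <- max(min(xs), 1e-3)
  fit0 <- minpack.lm::nlsLM(
    xs ~ M * B / (B + exp(-4 * u / M) * (M - B)),
    start = list(M = M0, B = B0),
    lower = c(M = max(xs), B = 1e-6),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit0)
  a <- a0; M <- unname(cf["M"]); B <- unname(cf["B"])

  if (refine) {
    fit1 <- try(minpack.lm::nlsLM(
      x2 ~ a * M * B / (B + exp(-4 * u / M) * (M - B)),
      start = list(a = a, M = M, B = B),
      lower = c(a = 1e-6, M = 1e-3, B = 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
    if (!inherits(fit1, "try-error")) {
      cf <- stats::coef(fit1)
      a <- unname(cf["a"]); M <- unname(cf["M"]); B <- unname(cf["B"])
    }
  }
  pred <- a * M * B / (B + exp(-4 * u / M) * (M - B))
  structure(list(a = a, params = activationParams(M, B, a = a),
                 rss = sum((x2 - pred)^2)),
            class = "ActivationFit")
}

#' @export
print.ActivationFit <- function(x, ...) {
  cat(sprintf("<ActivationFit> a = %.4f, M = %.3f, B = %.3f (rss %.3e)\n",
              x$a, x$params$M, x$params$B, x$rss))
  invisible(x)
}

#' GPe steady state under constant drive and self-inhibition
#'
#' Solves `x = S2(u + c22 * x)` by damped fixed-point iteration
#' `x <- (1 - lambda) x + lambda S2(u + c22 x)` (`lambda = 0.5`), which
#' converges whenever the contraction condition `c22 * l2 < 1` holds
#' (`l2` the maximum slope of `S2`). Note the self-term enters with a
#' positive sign here, matching the disconnected-GPe identification setup in
#' which `u` aggregates all signed inputs.
#'
#' @param S2 [activationParams()] of the GPe.
#' @param c22 Self-coupling (`>= 0`).
#' @param u Constant drive.
#' @param tol Residual tolerance.
#' @param maxIter Iteration cap.
#' @return Fixed point `x2*` with residual below `tol`.
#' @export
gpeSteadyState <- function(S2, c22, u, tol = 1e-10, maxIter = 1e4) {
  .gpeSteadyStateVec(S2, c22, u, tol, maxIter)
}

# vectorized over u; shared by gpeSteadyState and estimateC22
.gpeSteadyStateVec <- function(S2, c22, u, tol = 1e-10, maxIter = 1e4) {
  stopifnot(inherits(S2, "ActivationParams"), c22 >= 0)
  amp <- S2$a * S2$M; k <- 4 / S2$M; o <- log((S2$M - S2$B) / S2$B)
  S <- function(x) amp * stats::plogis(k * x - o)
  x <- S(u)
  lambda <- 0.5
  for (i in seq_len(maxIter)) {
    xn <- (1 - lambda) * x + lambda * S(u + c22 * x)
    if (max(abs(xn - x)) < tol / 4 &&
        max(abs(xn - S(u + c22 * xn))) < tol) return(xn)
    x <- xn
  }
  l2 <- activationMaxSlope(S2)
  stop(sprintf("fixed-point iteration did not converge: c22 * l2 = %.3f (contraction requires < 1)",
               c22 * l2))
}

#' Estimate the GPe self-coupling by normalized least squares
#'
#' For each candidate `c22` on the grid, predicts the GPe steady state for
#' every observed STN drive via [gpeSteadyState()] and evaluates the
#' normalized square error
#' \deqn{nLSQ(c_{22}) = \frac{\sum_i (f_{c_{22}}(u_i) - x_{2,i})^2}{\sum_i x_{2,i}^2}.}
#' Returns the grid minimizer; ties break toward the smaller `c22`.
#'
#' @param S2 Identified GPe [activationParams()] (scale included).
#' @param pairs [ratePairs()] measured with the self-coupling present.
#' @param grid Candidate `c22` values; default `seq(0, 0.9 / l2, 0.01)`,
#'   inside the contraction region.
#' @return List of class `IdentificationResult`: `c22`, `nlsq`, plus the
#'   full `grid` and `nlsqValues` profiles.
#' @export
estimateC22 <- function(S2, pairs, grid = NULL) {
  stopifnot(inherits(S2, "ActivationParams"), inherits(pairs, "RatePairs"))
  if (is.null(grid)) {
    l2 <- activationMaxSlope(S2)
    grid <- seq(0, 0.9 / l2, by = 0.01)
  }
  if (length(grid) == 0) stop("empty candidate grid")
  denom <- sum(pairs$x2^2)
  nlsq <- vapply(grid, function(cc) {
    pred <- .gpeSteadyStateVec(S2, cc, pairs$u)
    sum((pred - pairs$x2)^2) / denom
  }, numeric(1))
  i <- which.min(nlsq)   # first minimum = smallest c22 on an ascending grid
  structure(list(c22 = grid[i], nlsq = nlsq[i], grid = grid,
                 nlsqValues = nlsq),
            class = "IdentificationResult")
}

#' @export
print.IdentificationResult <- function(x, ...) {
  cat(sprintf("<IdentificationResult> c22 = %g (nLSQ = %.3e over %d candidates)\n",
              x$c22, x$nlsq, length(x$grid)))
  invisible(x)
}

#' Stabilizability criterion for the self-tuning controller
#'
#' The loop is stabilizable by STN-only stimulation when the GPe does not
#' pace itself: `c22 * l2 < 1`, with `l2` the maximum slope of the GPe
#' activation.
#'
#' @param c22 GPe self-coupling (`>= 0`).
#' @param l2 Maximum activation slope (`>= 0`).
#' @return List with `satisfied` (logical) and `margin` (`1 - c22 * l2`).
#' @export
stabilizabilityCheck <- function(c22, l2) {
  stopifnot(c22 >= 0, l2 >= 0)
  list(satisfied = c22 * l2 < 1, margin = 1 - c22 * l2)
}
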