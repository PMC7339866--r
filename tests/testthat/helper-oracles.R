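# Independent oracles used across the suite.

# Method-of-steps solution of x'(t) = -x(t - 1), constant history 1, by
# piecewise analytic integration of the delayed term interval by interval:
# on [0,1] x(t) = 1 - t; on [1,2] x(t) = 1 - t + (t-1)^2/2; on [2,3] the
# same plus -(t-2)^3/6.
methodOfStepsOracle <- function(t) {
  # valid for t in [0, 3]
  vapply(t, function(ti) {
    if (ti <= 1) 1 - ti
    else if (ti <= 2) 1 - ti + (ti - 1)^2 / 2
    else 1 - ti + (ti - 1)^2 / 2 - (ti - 2)^3 / 6
  }, numeric(1))
}

# damped fixed-point iteration for the loop equilibrium (independent of the
# nested-bisection solver in the package)
dampedEquilibriumOracle <- function(p, u1bar, u2bar, lambda = 0.3,
                                    iters = 50000) {
  x1 <- 20; x2 <- 60
  for (i in seq_len(iters)) {
    n1 <- activation(p$S1, p$c11 * x1 - p$c12 * x2 + p$b1 * u1bar)
    n2 <- activation(p$S2, p$c21 * x1 - p$c22 * x2 - p$b2 * u2bar)
    x1 <- (1 - lambda) * x1 + lambda * n1
    x2 <- (1 - lambda) * x2 + lambda * n2
  }
  c(x1, x2)
}

# trapezoidal recomputation used to cross-check the metric integrals
trapzOracle <- function(v, dt) {
  n <- length(v)
  sum((v[-1] + v[-n]) / 2) * dt / ((n - 1) * dt)
}

# standard perturbed-equilibrium start that excites a limit cycle if present
perturbedHistory <- function(p, u1bar, u2bar = 2) {
  eq <- findEquilibrium(p, u1bar, u2bar)
  c(eq$x1 * 1.05 + 0.5, eq$x2)
}

# beta-band peak-to-peak of a trajectory tail, measured on a 1 kHz resample
steadyBetaAmp <- function(tr, fromMs) {
  dt <- attr(tr, "dt")
  stride <- round(1 / dt)
  i <- which(tr$t_ms > fromMs)
  i <- i[seq(1, length(i), by = stride)]
  x <- tr$x1[i]
  betaDrive(x - mean(x), fs = 1000)
}
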