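#' Parameters of the delayed STN-GPe firing-rate loop
#'
#' The two-population model
#' \deqn{\tau_1 \dot x_1(t) = -x_1(t) + S_1(c_{11} x_1(t-\delta_{11}) - c_{12} x_2(t-\delta_{12}) + b_1 u_1(t) + \mu(t))}
#' \deqn{\tau_2 \dot x_2(t) = -x_2(t) + S_2(c_{21} x_1(t-\delta_{21}) - c_{22} x_2(t-\delta_{22}) - b_2 u_2(t))}
#' where `x1` is the STN rate, `x2` the GPe rate (pulses/s), `u1`/`u2` the
#' cortical and striatal inputs, and `mu` the stimulation term entering the
#' STN activation argument. All couplings are non-negative; excitatory and
#' inhibitory signs are structural.
#'
#' Defaults are the constants used throughout the loop's standard
#' parameterization: `tau1 = 6`, `tau2 = 14` ms, `delta12 = delta21 = 6`,
#' `delta22 = 4` ms, STN activation `(M, B) = (300, 17)`, GPe activation
#' `(M, B) = (400, 75)`, and no STN self-coupling (`c11 = delta11 = 0`).
#'
#' @param c12,c21,c22 Coupling strengths (dimensionless, `>= 0`): GPe->STN,
#'   STN->GPe, GPe->GPe.
#' @param b1,b2 Input weights (dimensionless, `>= 0`).
#' @param c11,delta11 STN self-coupling and its delay (default 0).
#' @param tau1,tau2 Membrane time constants (ms, `> 0`).
#' @param delta12,delta21,delta22 Transmission delays (ms, `>= 0`).
#' @param S1,S2 [activationParams()] for STN and GPe.
#' @return An object of class `LoopParams`.
#' @export
loopParams <- function(c12, c21, c22, b1, b2,
                       c11 = 0, delta11 = 0,
                       tau1 = 6, tau2 = 14,
                       delta12 = 6, delta21 = 6, delta22 = 4,
                       S1 = activationParams(300, 17),
                       S2 = activationParams(400, 75)) {
  cs <- c(c11 = c11, c12 = c12, c21 = c21, c22 = c22, b1 = b1, b2 = b2)
  if (any(cs < 0)) stop("couplings and input weights must be non-negative")
  if (!(tau1 > 0 && tau2 > 0)) stop("time constants must be positive")
  if (any(c(delta11, delta12, delta21, delta22) < 0)) stop("delays must be non-negative")
  stopifnot(inherits(S1, "ActivationParams"), inherits(S2, "ActivationParams"))
  structure(list(c11 = c11, c12 = c12, c21 = c21, c22 = c22,
                 b1 = b1, b2 = b2, tau1 = tau1, tau2 = tau2,
                 delta11 = delta11, delta12 = delta12, delta21 = delta21,
                 delta22 = delta22, S1 = S1, S2 = S2),
            class = "LoopParams")
}

#' @export
print.LoopParams <- function(x, ...) {
  cat("<LoopParams>\n")
  cat(sprintf("  couplings: c11 = %g, c12 = %g, c21 = %g, c22 = %g\n",
              x$c11, x$c12, x$c21, x$c22))
  cat(sprintf("  inputs:    b1 = %g, b2 = %g\n", x$b1, x$b2))
  cat(sprintf("  dynamics:  tau = (%g, %g) ms, delays = (%g, %g, %g, %g) ms\n",
              x$tau1, x$tau2, x$delta11, x$delta12, x$delta21, x$delta22))
  cat(sprintf("  S1: M = %g, B = %g, a = %g;  S2: M = %g, B = %g, a = %g\n",
              x$S1$M, x$S1$B, x$S1$a, x$S2$M, x$S2$B, x$S2$a))
  invisible(x)
}

#' Standard loop parameterizations
#'
#' Named presets for the two oscillation regimes studied with this model:
#' `"endogenous"` (strong reciprocal coupling; the loop self-oscillates in
#' the beta band under constant input) and `"exogenous"` (weak coupling; the
#' loop is stable and entrainable, amplifying oscillatory cortical input).
#' `"sweep"` is the template used for oscillation maps over `(c12, c21)`.
#'
#' @param regime One of `"endogenous"`, `"exogenous"`, `"sweep"`.
#' @return A [loopParams()] object.
#' @export
loopPreset <- function(regime = c("endogenous", "exogenous", "sweep")) {
  regime <- match.arg(regime)
  switch(regime,
    endogenous = loopParams(c12 = 3, c21 = 10, c22 = 0.9, b1 = 5, b2 = 139.4),
    exogenous  = loopParams(c12 = 1.12, c21 = 19, c22 = 0.9, b1 = 2.42, b2 = 15.1),
    sweep      = loopParams(c12 = 0, c21 = 0, c22 = 4, b1 = 8, b2 = 139.4))
}
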