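#' DBS controller configuration
#'
#' Control laws available for the firing-rate loop and the surrogate plant:
#' \describe{
#'   \item{`off`}{no stimulation, `mu = 0`.}
#'   \item{`proportional`}{fixed gain, `mu = -theta * s` where `s` is the
#'     measured deviation (negative feedback on the firing-rate model) or
#'     `mu = +theta * s` on the plant (positive feedback on the biomarker).}
#'   \item{`adaptive_abs`}{self-tuning gain driven by the rectified deviation:
#'     `tau_theta * dtheta/dt = |x1 - x1bar| - sigma * theta`.}
#'   \item{`adaptive_beta`}{self-tuning gain driven by a beta biomarker, the
#'     peak-to-peak amplitude of the 15-30 Hz band-passed STN deviation
#'     (Butterworth, order 5) over the trailing 500 ms window.}
#'   \item{`adaptive_arv`}{plant-facing self-tuning law driven by the
#'     half-wave-rectified tracking error between the measured beta ARV and a
#'     target level; stimulation is positive feedback on the biomarker.}
#' }
#' The dissipation term `-sigma * theta` is the sigma-modification leakage:
#' the gain settles near the minimal effective value and decays when the
#' drive vanishes.
#'
#' @param mode One of `"off"`, `"proportional"`, `"adaptive_abs"`,
#'   `"adaptive_beta"`, `"adaptive_arv"`.
#' @param theta Fixed gain (proportional mode).
#' @param theta0 Initial gain for adaptive modes (`>= 0`).
#' @param tauTheta Gain time constant (ms, `> 0`).
#' @param sigma Leakage coefficient (dimensionless, `>= 0`).
#' @param target Target biomarker level (`adaptive_arv`), biomarker units.
#' @param windowMs Biomarker window length (ms) for `adaptive_beta`.
#' @param bandHz Passband (Hz) of the beta biomarker filter.
#' @param filterOrder Butterworth order of the biomarker filter.
#' @param tOnMs Time (ms) at which stimulation (and gain adaptation) switches
#'   on; before that `mu = 0` and `theta` is held.
#' @param sign Feedback sign convention: `"negative"` (firing-rate model) or
#'   `"positive"` (plant biomarker).
#' @return An object of class `ControllerConfig`.
#' @export
controllerConfig <- function(mode = c("off", "proportional", "adaptive_abs",
                                      "adaptive_beta", "adaptive_arv"),
                             theta = 0, theta0 = 0, tauTheta = 75, sigma = 0.19,
                             target = 0, windowMs = 500, bandHz = c(15, 30),
                             filterOrder = 5, tOnMs = 0,
                             sign = c("negative", "positive")) {
  mode <- match.arg(mode)
  sign <- match.arg(sign)
  if (mode == "adaptive_arv") sign <- "positive"
  stopifnot(tauTheta > 0, sigma >= 0, theta0 >= 0, theta >= 0, windowMs > 0)
  structure(list(mode = mode, theta = theta, theta0 = theta0,
                 tauTheta = tauTheta, sigma = sigma, target = target,
                 windowMs = windowMs, bandHz = bandHz,
                 filterOrder = filterOrder, tOnMs = tOnMs, sign = sign),
            class = "ControllerConfig")
}

#' @rdname controllerConfig
#' @export
controllerOff <- function() controllerConfig("off")

#' @rdname controllerConfig
#' @export
controllerProportional <- function(theta, tOnMs = 0, sign = "negative")
  controllerConfig("proportional", theta = theta, tOnMs = tOnMs, sign = sign)

#' @rdname controllerConfig
#' @export
controllerAdaptive <- function(mode = c("adaptive_beta", "adaptive_abs"),
                               tauTheta = 75, sigma = 0.19, theta0 = 0,
                               tOnMs = 0, windowMs = 500, bandHz = c(15, 30),
                               filterOrder = 5)
  controllerConfig(match.arg(mode), tauTheta = tauTheta, sigma = sigma,
                   theta0 = theta0, tOnMs = tOnMs, windowMs = windowMs,
                   bandHz = bandHz, filterOrder = filterOrder)

#' @rdname controllerConfig
#' @export
controllerARV <- function(target, tauTheta = 100, sigma = 0.00875, theta0 = 0,
                          tOnMs = 0)
  controllerConfig("adaptive_arv", target = target, tauTheta = tauTheta,
                   sigma = sigma, theta0 = theta0, tOnMs = tOnMs)

#' @export
print.ControllerConfig <- function(x, ...) {
  cat(sprintf("<ControllerConfig> mode = %s", x$mode))
  if (x$mode == "proportional") cat(sprintf(", theta = %g", x$theta))
  if (startsWith(x$mode, "adaptive"))
    cat(sprintf(", tauTheta = %g ms, sigma = %g, theta0 = %g",
                x$tauTheta, x$sigma, x$theta0))
  cat(sprintf(", on at %g ms\n", x$tOnMs))
  invisible(x)
}

#' Instantaneous controller output
#'
#' `mu = -theta * signal` under the negative-feedback convention (stimulation
#' counteracting the STN deviation), `mu = +theta * signal` under the
#' positive-feedback convention used on the stimulation plant, and 0 when the
#' controller is off.
#'
#' @param cfg A [controllerConfig()].
#' @param theta Current gain (`>= 0`).
#' @param signal Measured value (deviation or biomarker).
#' @return Stimulation magnitude `mu`.
#' @export
controllerOutput <- function(cfg, theta, signal) {
  stopifnot(inherits(cfg, "ControllerConfig"), theta >= 0)
  if (cfg$mode == "off") return(0 * signal)
  if (cfg$sign == "negative") -theta * signal else theta * signal
}

#' One explicit-Euler update of the self-tuning gain
#'
#' Discretizes `tau_theta * dtheta/dt = drive - sigma * theta`. The gain is
#' clamped at zero after the step: the continuous-time law keeps `theta >= 0`
#' for non-negative drive, and clamping removes discretization undershoot.
#'
#' @param theta Current gain.
#' @param drive Non-negative drive (`|x1|`, beta amplitude, or rectified
#'   tracking error depending on the mode).
#' @param sigma,tauTheta Leakage coefficient and gain time constant (ms).
#' @param dt Step (ms), small relative to `tauTheta`.
#' @return Updated gain, `>= 0`.
#' @export
adaptiveGainStep <- function(theta, drive, sigma, tauTheta, dt) {
  stopifnot(drive >= 0, tauTheta > 0, sigma >= 0, dt > 0)
  max(0, theta + dt * (drive - sigma * theta) / tauTheta)
}

#' Beta biomarker drive from an STN rate window
#'
#' Peak-to-peak amplitude of the causally band-passed signal (Butterworth,
#' order `filterOrder`, `bandHz`) over the trailing `windowMs` of the series.
#' The filter runs over the whole provided history so its transient is
#' outside the measured window whenever enough history is supplied.
#'
#' @param x1 Sampled STN deviation covering at least the trailing window.
#' @param fs Sampling rate (Hz).
#' @param bandHz Passband edges (Hz).
#' @param filterOrder Butterworth order.
#' @param windowMs Window length (ms).
#' @return Non-negative scalar beta drive.
#' @export
betaDrive <- function(x1, fs, bandHz = c(15, 30), filterOrder = 5,
                      windowMs = 500) {
  nwin <- round(windowMs * fs / 1000)
  if (length(x1) < nwin)
    stop(sprintf("beta drive needs at least %d samples (%g ms at %g Hz)",
                 nwin, windowMs, fs))
  spec <- filterSpec("butterworth", order = filterOrder, bandHz = bandHz, fs = fs)
  y <- bandpass(x1, spec, mode = "causal")
  w <- y[(length(y) - nwin + 1L):length(y)]
  diff(range(w))
}

#' Half-wave rectified tracking error
#'
#' Drive of the plant-facing adaptive law: the excess of the measured
#' biomarker over the target, zero when the biomarker is at or below target.
#' With `normalized = TRUE` the excess is expressed relative to the target.
#'
#' @param biomarker Measured beta ARV (`>= 0`).
#' @param target Target suppression level (`>= 0`).
#' @param normalized Divide by the target (scale-free error)?
#' @return Non-negative drive.
#' @export
errorDrive <- function(biomarker, target, normalized = FALSE) {
  stopifnot(all(biomarker >= 0), all(target >= 0))
  if (normalized && any(target == 0))
    stop("normalized error drive requires a positive target")
  e <- pmax(biomarker - target, 0)
  if (normalized) e / target else e
}

#' Analytic upper estimate of the minimal stabilizing gain
#'
#' The conservative bound
#' \deqn{\theta^* \le 8\left(c_{11}^2 + \frac{4 c_{21}^2 c_{12}^2}{(1 - c_{22})^2}\right)}
#' on the minimal proportional gain guaranteeing exponential suppression,
#' valid in the normalized-slope convention and undefined at `c22 = 1`.
#'
#' @param c11,c12,c21,c22 Coupling strengths.
#' @return Object of class `GainBound` (list with `bound`).
#' @export
thetaStarBound <- function(c12, c21, c22, c11 = 0) {
  if (c22 == 1) stop("theta* bound is undefined at c22 = 1")
  b <- 8 * (c11^2 + 4 * c21^2 * c12^2 / (1 - c22)^2)
  structure(list(bound = b, c11 = c11, c12 = c12, c21 = c21, c22 = c22),
            class = "GainBound")
}

#' @export
print.GainBound <- function(x, ...) {
  cat(sprintf("<GainBound> theta* <= %g (conservative estimate)\n", x$bound))
  invisible(x)
}
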