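#' Band-pass filter specification
#'
#' Describes the biomarker extraction filters: Butterworth (maximally flat)
#' or Chebyshev type I (equiripple passband, ripple `rippleDb`). The band may
#' be given as explicit edges or as center + bandwidth.
#'
#' @param family `"butterworth"` or `"chebyshev1"`.
#' @param order Filter order (`>= 1`).
#' @param bandHz Passband edges `c(low, high)` in Hz, or `NULL` if
#'   `centerHz`/`bandwidthHz` are given.
#' @param centerHz,bandwidthHz Alternative band parameterization.
#' @param fs Sampling rate (Hz).
#' @param rippleDb Passband ripple (dB) for Chebyshev designs.
#' @return An object of class `FilterSpec`.
#' @export
filterSpec <- function(family = c("butterworth", "chebyshev1"), order,
                       bandHz = NULL, centerHz = NULL, bandwidthHz = NULL,
                       fs, rippleDb = 0.5) {
  family <- match.arg(family)
  stopifnot(order >= 1, fs > 0)
  if (is.null(bandHz)) {
    if (is.null(centerHz) || is.null(bandwidthHz))
      stop("give either bandHz or centerHz + bandwidthHz")
    bandHz <- centerHz + c(-0.5, 0.5) * bandwidthHz
  }
  if (!(bandHz[1] > 0 && bandHz[2] < fs / 2 && bandHz[1] < bandHz[2]))
    stop(sprintf("passband [%g, %g] Hz must lie inside (0, Nyquist = %g) Hz",
                 bandHz[1], bandHz[2], fs / 2))
  structure(list(family = family, order = order, bandHz = bandHz, fs = fs,
                 rippleDb = rippleDb),
            class = "FilterSpec")
}

# signal-package filter object for a spec
.designFilter <- function(spec) {
  W <- spec$bandHz / (spec$fs / 2)
  if (spec$family == "butterworth")
    signal::butter(spec$order, W, type = "pass")
  else
    signal::cheby1(spec$order, spec$rippleDb, W, type = "pass")
}

#' Band-pass filter a sampled series
#'
#' `mode = "causal"` applies the IIR filter forward only (as a real-time
#' controller must); `mode = "zero-phase"` uses forward-backward filtering
#' for offline analyses where phase distortion matters.
#'
#' @param x Sampled series (length well above `3 * order`).
#' @param spec A [filterSpec()].
#' @param mode `"causal"` or `"zero-phase"`.
#' @return Filtered series, same length as `x`.
#' @export
bandpass <- function(x, spec, mode = c("causal", "zero-phase")) {
  stopifnot(inherits(spec, "FilterSpec"))
  mode <- match.arg(mode)
  if (length(x) <= 3 * spec$order)
    stop("series too short for the requested filter order")
  flt <- .designFilter(spec)
  y <- if (mode == "causal") signal::filter(flt, x) else signal::filtfilt(flt, x)
  as.numeric(y)
}

#' Sliding-window peak-to-peak envelope
#'
#' At each sample, `max - min` of the signal over the trailing window; the
#' instantaneous oscillation amplitude measure used for rate trajectories.
#' Samples whose trailing window would start before the series use the
#' available partial window.
#'
#' @param x Sampled series.
#' @param fs Sampling rate (Hz).
#' @param windowMs Window length (ms), at most the series span.
#' @return Envelope series, same length as `x` (0 for constant signals).
#' @export
slidingPeakToPeak <- function(x, fs, windowMs = 100) {
  n <- length(x)
  k <- max(1L, round(windowMs * fs / 1000))
  if (k > n) stop("window exceeds the series span")
  vapply(seq_len(n), function(i) {
    w <- x[max(1L, i - k + 1L):i]
    max(w) - min(w)
  }, numeric(1))
}

#' Average rectified value of a band-filtered signal per epoch
#'
#' The beta ARV biomarker: the signal is causally band-pass filtered with
#' `spec`, then the mean absolute value is taken over consecutive
#' non-overlapping epochs of `epochMs` (right-aligned; a trailing partial
#' epoch is dropped).
#'
#' @param x LFP-like sampled series.
#' @param spec A [filterSpec()] (e.g. Chebyshev-I order 4, 21-29 Hz).
#' @param epochMs Epoch length (ms).
#' @return Data frame with `t_ms` (epoch end time) and `arv`.
#' @export
betaARV <- function(x, spec, epochMs = 100) {
  stopifnot(inherits(spec, "FilterSpec"), epochMs > 0)
  y <- abs(bandpass(x, spec, mode = "causal"))
  k <- max(1L, round(epochMs * spec$fs / 1000))
  nep <- floor(length(y) / k)
  if (nep < 1) stop("series shorter than one epoch")
  arv <- vapply(seq_len(nep), function(j) mean(y[((j - 1L) * k + 1L):(j * k)]),
                numeric(1))
  data.frame(t_ms = seq_len(nep) * k * 1000 / spec$fs, arv = arv)
}

# trapezoidal time-average of f(t) over a uniform grid
.trapzMean <- function(v, dt) {
  n <- length(v)
  if (n < 2) return(v[1])
  sum((v[-1] + v[-n]) / 2) * dt / ((n - 1) * dt)
}

#' Mean squared tracking error
#'
#' Time-average of the squared error series over the simulation span,
#' `MSE = (1/Tsim) integral e(t)^2 dt`, computed by the trapezoidal rule.
#' Scenario reports express it as a percentage of a reference (stimulation
#' off) MSE.
#'
#' @param e Error series on a uniform grid (conventionally the normalized
#'   error `(biomarker - target) / target`).
#' @param dt Grid step (any time unit; the average is unit-free).
#' @return Non-negative scalar.
#' @export
meanSquaredError <- function(e, dt) {
  stopifnot(dt > 0)
  .trapzMean(e^2, dt)
}

#' Mean electrical power delivered by the stimulator
#'
#' `PC = (1/Tsim) integral Z_E(t) I_DBS(t)^2 dt` by the trapezoidal rule.
#' With impedance in kilo-ohm and current in milliampere the product is in
#' milliwatt; the result is returned in microwatt (factor 1000).
#'
#' @param iDbs Stimulation current series (mA).
#' @param zE Electrode impedance series (kOhm), same grid, all `> 0`.
#' @param dt Grid step.
#' @return Mean power in microwatt.
#' @export
powerConsumption <- function(iDbs, zE, dt) {
  if (length(zE) == 1) zE <- rep_len(zE, length(iDbs))
  stopifnot(length(iDbs) == length(zE), dt > 0)
  if (any(zE < 0)) stop("electrode impedance must be non-negative")
  1000 * .trapzMean(zE * iDbs^2, dt)
}
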