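#' Dominant frequency of a sampled signal
#'
#' Frequency of the largest non-DC spectral peak after discarding an initial
#' transient. Returns `NA` (with a `"bin_hz"` attribute still attached) for a
#' flat signal rather than 0.
#'
#' @param x Sampled series.
#' @param fs Sampling rate (Hz).
#' @param transientMs Initial span to discard (ms).
#' @return Peak frequency (Hz) with attribute `bin_hz` (the FFT resolution),
#'   or `NA` for a flat signal.
#' @export
dominantFrequency <- function(x, fs, transientMs = 1000) {
  ndrop <- round(transientMs * fs / 1000)
  if (ndrop >= length(x) - 8) stop("series too short after transient discard")
  if (ndrop > 0) x <- x[-seq_len(ndrop)]
  x <- x - mean(x)
  n <- length(x)
  binHz <- fs / n
  if (stats::sd(x) < 1e-10 * (1 + abs(mean(x))))
    return(structure(NA_real_, bin_hz = binHz))
  pw <- Mod(stats::fft(x))^2
  idx <- 2:(floor(n / 2))
  f <- (idx - 1) * binHz
  structure(f[which.max(pw[idx])], bin_hz = binHz)
}

#' Beta-band oscillation map over STN-GPe coupling space
#'
#' Simulates the loop on a grid of `(c12, c21)` couplings under constant
#' inputs and measures, per cell and population, the steady-state beta-band
#' oscillation amplitude: the zero-phase band-passed rate's peak-to-peak over
#' the final `steadyMs` of each run. Amplitudes are normalized to `[0, 1]`
#' separately per population panel.
#'
#' @param p Template [loopParams()]; its `c12`/`c21` are replaced per cell.
#' @param c12Values,c21Values Grid values (within the regime's 0-4 and 0-32
#'   ranges for the standard sweep template).
#' @param u1bar,u2bar Constant input levels.
#' @param filter A [filterSpec()] at the 1 kHz measurement rate; default
#'   Butterworth order 5, 16-24 Hz.
#' @param duration,steadyMs,dt Simulation span, steady-state window and step
#'   (ms).
#' @return A `SweepResult`: long data frame `(c12, c21, population,
#'   amplitude, amplitude_norm, failed)` with per-panel maxima in attribute
#'   `panel_max`.
#' @export
oscillationMap <- function(p, c12Values, c21Values, u1bar = 27, u2bar = 2,
                           filter = NULL, duration = 5000, steadyMs = 2000,
                           dt = 0.1) {
  stopifnot(inherits(p, "LoopParams"))
  if (steadyMs >= duration)
    stop("steadyMs must be shorter than the simulation duration")
  # rates are band-limited well below 500 Hz, so amplitude extraction runs on
  # a 1 kHz resample where the narrow-band IIR design is well conditioned
  stride <- max(1L, round(1 / dt))
  fsMeas <- 1000 / (dt * stride)
  if (is.null(filter))
    filter <- filterSpec("butterworth", order = 5, centerHz = 20,
                         bandwidthHz = 8, fs = fsMeas)
  nsteady <- round(steadyMs * fsMeas / 1000)
  rows <- list()
  for (c12 in c12Values) for (c21 in c21Values) {
    pc <- p; pc$c12 <- c12; pc$c21 <- c21
    amp <- c(NA_real_, NA_real_); failed <- FALSE
    tr <- tryCatch({
      # start slightly off equilibrium so a limit cycle, if any, is excited
      eq <- findEquilibrium(pc, u1bar, u2bar)
      simulateLoop(pc, u1 = inputConstant(u1bar), u2 = inputConstant(u2bar),
                   duration = duration, dt = dt,
                   history = c(eq$x1 * 1.05 + 0.5, eq$x2))
    }, error = function(e) NULL)
    if (is.null(tr)) failed <- TRUE else {
      keep <- seq(1L, nrow(tr), by = stride)
      tail_idx <- (length(keep) - nsteady + 1L):length(keep)
      for (j in 1:2) {
        xs <- tr[[c("x1", "x2")[j]]][keep]
        y <- bandpass(xs - mean(xs), filter, mode = "zero-phase")
        amp[j] <- diff(range(y[tail_idx]))
        if (!is.finite(amp[j])) failed <- TRUE
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      c12 = c12, c21 = c21, population = c("STN", "GPe"),
      amplitude = amp, failed = failed)
  }
  res <- do.call(rbind, rows)
  pmax_ <- tapply(res$amplitude, res$population, max, na.rm = TRUE)
  res$amplitude_norm <- res$amplitude / pmax_[res$population]
  class(res) <- c("SweepResult", "data.frame")
  attr(res, "panel_max") <- pmax_
  res
}

#' Magnitude of the linearized delayed transfer function
#'
#' Closed-form small-signal gain of the loop about its equilibrium for a
#' cortical input at frequency `f`: with `s = i 2 pi f` and `ai` the
#' activation slopes at the equilibrium arguments,
#' \deqn{H_1(s) = \frac{a_1 b_1}{\tau_1 s + 1 - a_1 c_{11} e^{-s\delta_{11}}
#'   + a_1 c_{12} e^{-s\delta_{12}} G(s)}, \quad
#'   G(s) = \frac{a_2 c_{21} e^{-s\delta_{21}}}{\tau_2 s + 1 + a_2 c_{22} e^{-s\delta_{22}}},}
#' and `H_2 = G H_1`. Delays enter as pure phase factors.
#'
#' @param p A [loopParams()].
#' @param u1bar,u2bar Constant operating-point inputs.
#' @param freqsHz Frequencies (Hz).
#' @return Data frame `(freq_hz, gain_x1, gain_x2)`: steady-state amplitude
#'   of `x1`/`x2` per unit amplitude of `u1`.
#' @export
linearizedGain <- function(p, u1bar, u2bar = 2, freqsHz) {
  eq <- findEquilibrium(p, u1bar, u2bar)
  q1 <- p$c11 * eq$x1 - p$c12 * eq$x2 + p$b1 * u1bar
  q2 <- p$c21 * eq$x1 - p$c22 * eq$x2 - p$b2 * u2bar
  a1 <- activationSlope(p$S1, q1)
  a2 <- activationSlope(p$S2, q2)
  s <- 1i * 2 * pi * freqsHz / 1000   # rad/ms
  G <- a2 * p$c21 * exp(-s * p$delta21) /
    (p$tau2 * s + 1 + a2 * p$c22 * exp(-s * p$delta22))
  H1 <- a1 * p$b1 /
    (p$tau1 * s + 1 - a1 * p$c11 * exp(-s * p$delta11) +
       a1 * p$c12 * exp(-s * p$delta12) * G)
  data.frame(freq_hz = freqsHz, gain_x1 = Mod(H1), gain_x2 = Mod(G * H1))
}

#' Nonlinear frequency-response (Bode) profile of the loop
#'
#' For each input frequency the loop is driven by a sinusoidal cortical
#' input, simulated to steady state, and the per-population amplitude ratio
#' is measured as half the steady-state peak-to-peak divided by the input
#' amplitude. Each frequency reuses the previous frequency's final state as
#' initial history (warm start) to shorten settling. A cell is flagged
#' non-entrained when the steady-state dominant frequency differs from the
#' input frequency by more than one FFT bin.
#'
#' @param p A [loopParams()] in the entrainable (stable) regime.
#' @param freqsHz Input frequencies (Hz), increasing.
#' @param inputMean,inputAmplitude Sinusoid mean and amplitude.
#' @param controller Optional [controllerConfig()]; `NULL` means DBS off.
#' @param u2bar Constant striatal level.
#' @param settleMs Settling span discarded before measuring (ms).
#' @param measureMs Measurement span; defaults to at least 8 input periods.
#' @param dt Step (ms).
#' @return A `BodeResult`: long data frame
#'   `(freq_hz, population, ratio, controller, entrained)`.
#' @export
bodeProfile <- function(p, freqsHz, inputMean, inputAmplitude,
                        controller = NULL, u2bar = 2,
                        settleMs = 2000, measureMs = NULL, dt = 0.1) {
  stopifnot(inherits(p, "LoopParams"), !is.unsorted(freqsHz))
  if (is.null(controller)) controller <- controllerOff()
  eq <- findEquilibrium(p, inputMean, u2bar)
  hist <- c(eq$x1, eq$x2)
  fs <- 1000 / dt
  rows <- list()
  for (f in freqsHz) {
    mspan <- if (is.null(measureMs)) max(1000, ceiling(8 * 1000 / f)) else measureMs
    dur <- settleMs + mspan
    tr <- simulateLoop(p, u1 = inputSinusoid(f, inputMean, inputAmplitude),
                       u2 = inputConstant(u2bar), controller = controller,
                       duration = dur, dt = dt, history = hist,
                       xref = c(eq$x1, eq$x2))
    idx <- tr$t_ms > settleMs
    ratios <- c(diff(range(tr$x1[idx])) / 2, diff(range(tr$x2[idx])) / 2) /
      inputAmplitude
    df <- dominantFrequency(tr$x1[idx], fs, transientMs = 0)
    entr <- is.finite(df) && abs(df - f) <= attr(df, "bin_hz") + 1e-9
    rows[[length(rows) + 1L]] <- data.frame(
      freq_hz = f, population = c("STN", "GPe"), ratio = ratios,
      controller = if (controller$mode == "off") "off" else "self-tuning",
      entrained = entr)
    hist <- c(tr$x1[nrow(tr)], tr$x2[nrow(tr)])   # warm start
  }
  res <- do.call(rbind, rows)
  class(res) <- c("BodeResult", "data.frame")
  res
}
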