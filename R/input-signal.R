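#' Input signals for the firing-rate loop
#'
#' Constructors for the exogenous inputs `u1` (cortical) and `u2` (striatal):
#' constant levels, sinusoids (optionally with a mid-run change of mean and
#' amplitude), piecewise-constant schedules, and sampled series.
#'
#' @param level Constant level (pulses/s).
#' @return An object of class `InputSignal`.
#' @export
inputConstant <- function(level) {
  stopifnot(is.numeric(level), length(level) == 1, is.finite(level))
  structure(list(kind = "constant", level = level), class = "InputSignal")
}

#' @rdname inputConstant
#' @param freqHz Oscillation frequency (Hz).
#' @param mean,amplitude Mean level and oscillation amplitude.
#' @param switchMs Optional time (ms) at which mean/amplitude change.
#' @param meanAfter,amplitudeAfter Levels after `switchMs`.
#' @export
inputSinusoid <- function(freqHz, mean, amplitude, switchMs = NULL,
                          meanAfter = mean, amplitudeAfter = amplitude) {
  stopifnot(freqHz > 0, amplitude >= 0)
  structure(list(kind = "sinusoid", freqHz = freqHz, mean = mean,
                 amplitude = amplitude, switchMs = switchMs,
                 meanAfter = meanAfter, amplitudeAfter = amplitudeAfter),
            class = "InputSignal")
}

#' @rdname inputConstant
#' @param breaksMs Increasing switch times (ms).
#' @param levels Levels on the intervals delimited by `breaksMs`
#'   (`length(levels) == length(breaksMs) + 1`).
#' @export
inputPiecewise <- function(breaksMs, levels) {
  stopifnot(length(levels) == length(breaksMs) + 1, !is.unsorted(breaksMs))
  structure(list(kind = "piecewise", breaksMs = breaksMs, levels = levels),
            class = "InputSignal")
}

#' @rdname inputConstant
#' @param timesMs,values Sample grid (ms) and values; evaluation linearly
#'   interpolates and must stay within the sampled span.
#' @export
inputSampled <- function(timesMs, values) {
  stopifnot(length(timesMs) == length(values), length(timesMs) >= 2,
            !is.unsorted(timesMs))
  structure(list(kind = "sampled", timesMs = timesMs, values = values),
            class = "InputSignal")
}

#' Evaluate an input signal
#'
#' @param sig An `InputSignal`.
#' @param t Time(s) in ms.
#' @return Signal value(s).
#' @export
inputValue <- function(sig, t) {
  inputFunction(sig)(t)
}

#' Compile an input signal into a fast function of time
#'
#' @param sig An `InputSignal`.
#' @return A vectorized function `f(t_ms)`.
#' @export
inputFunction <- function(sig) {
  stopifnot(inherits(sig, "InputSignal"))
  switch(sig$kind,
    constant = {
      lv <- sig$level
      function(t) rep_len(lv, length(t))
    },
    sinusoid = {
      w <- 2 * pi * sig$freqHz / 1000
      if (is.null(sig$switchMs)) {
        m <- sig$mean; A <- sig$amplitude
        function(t) m + A * sin(w * t)
      } else {
        s <- sig$switchMs
        m1 <- sig$mean; A1 <- sig$amplitude
        m2 <- sig$meanAfter; A2 <- sig$amplitudeAfter
        function(t) {
          pre <- t < s
          ifelse(pre, m1 + A1 * sin(w * t), m2 + A2 * sin(w * t))
        }
      }
    },
    piecewise = {
      br <- sig$breaksMs; lv <- sig$levels
      function(t) lv[findInterval(t, br) + 1L]
    },
    sampled = {
      tm <- sig$timesMs; v <- sig$values
      function(t) {
        if (any(t < tm[1] - 1e-9 | t > tm[length(tm)] + 1e-9))
          stop("sampled input evaluated outside its span")
        stats::approx(tm, v, xout = t, rule = 2)$y
      }
    })
}

# level used as the constant-input reference when computing the controller's
# equilibrium setpoint: the initial mean of the signal
.inputReferenceLevel <- function(sig) {
  switch(sig$kind,
    constant = sig$level,
    sinusoid = sig$mean,
    piecewise = sig$levels[1],
    sampled = sig$values[1])
}
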