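#' Integrator configuration for fixed-step DDE solving
#'
#' @param dt Step size (ms), `> 0`.
#' @param duration Total integration span (ms), `> 0`.
#' @param method Method tag; only `"rk4"` (explicit 4th-order Runge-Kutta with
#'   delayed terms taken from the history buffer, linearly interpolated at
#'   half-step stage times) is implemented.
#' @return An object of class `IntegratorConfig`.
#' @export
integratorConfig <- function(dt = 0.1, duration = 1000, method = "rk4") {
  stopifnot(is.numeric(dt), dt > 0, is.numeric(duration), duration > 0)
  method <- match.arg(method, "rk4")
  structure(list(dt = dt, duration = duration, method = method),
            class = "IntegratorConfig")
}

# delays must be non-negative integer multiples of dt; returns step counts
.delaySteps <- function(delays, dt) {
  if (any(delays < 0)) stop("delays must be non-negative")
  k <- delays / dt
  kr <- round(k)
  if (any(abs(k - kr) > 1e-8 * pmax(1, k)))
    stop(sprintf("every delay must be an integer multiple of dt = %g ms (got %s)",
                 dt, paste(delays[abs(k - kr) > 1e-8 * pmax(1, k)], collapse = ", ")))
  as.integer(kr)
}

#' History buffer over a uniform time grid
#'
#' Stores state samples on a uniform grid covering at least `[t - delta_max, t]`
#' so that delayed-state lookups never extrapolate.
#'
#' @param times Uniform, increasing time grid (ms).
#' @param states Numeric matrix, one row per time point, one column per state
#'   variable (a vector is treated as a single variable).
#' @return An object of class `HistoryBuffer`.
#' @export
historyBuffer <- function(times, states) {
  if (is.vector(states)) states <- matrix(states, ncol = 1)
  stopifnot(nrow(states) == length(times), length(times) >= 2)
  dt <- diff(times)
  if (max(abs(dt - dt[1])) > 1e-9 * max(1, abs(dt[1])))
    stop("history buffer requires a uniform time grid")
  structure(list(times = times, states = states, dt = dt[1]),
            class = "HistoryBuffer")
}

#' Look up a delayed state in a history buffer
#'
#' Returns the state at time `t - delta`. When the lag time falls on the grid
#' (always the case under the delay-commensurability rule) the stored sample
#' is returned exactly; off-grid times within the span are linearly
#' interpolated. Lookups outside the covered span are a hard error, never a
#' silent extrapolation.
#'
#' @param buffer A [historyBuffer()].
#' @param t Current time (ms).
#' @param delta Delay (ms), `>= 0`.
#' @return State vector at `t - delta`.
#' @export
lookupDelayed <- function(buffer, t, delta) {
  stopifnot(inherits(buffer, "HistoryBuffer"), delta >= 0)
  s <- t - delta
  tms <- buffer$times
  tol <- 1e-9 * max(1, abs(s))
  if (s < tms[1] - tol || s > tms[length(tms)] + tol)
    stop(sprintf("delayed lookup at t - delta = %g ms is outside the buffer span [%g, %g]",
                 s, tms[1], tms[length(tms)]))
  j <- (s - tms[1]) / buffer$dt
  jr <- round(j)
  if (abs(j - jr) < 1e-6) return(buffer$states[jr + 1, ])
  j0 <- floor(j)
  w <- j - j0
  (1 - w) * buffer$states[j0 + 1, ] + w * buffer$states[j0 + 2, ]
}

#' Integrate a system of delay differential equations
#'
#' Fixed-step explicit 4th-order Runge-Kutta for systems with multiple
#' constant discrete delays. Delayed terms are resolved from the solution
#' history: at full-step stage times the stored grid sample at exactly
#' `t - delta` is used; at half-step stage times the two bracketing samples
#' are linearly interpolated. Every delay must be an integer multiple of the
#' step, which is enforced rather than rounded.
#'
#' Non-delayed auxiliary state (e.g. a controller gain) is simply carried as
#' extra components of the state vector. Two hooks support coupled
#' discrete-time machinery: `rhs` receives an opaque `aux` value, and
#' `postStep(t, y, aux)` runs once after each accepted step and may modify
#' both the committed state and `aux` (used for gain clamping and streaming
#' biomarker filters).
#'
#' @param rhs Function `rhs(t, y, ylag, aux)` returning `dy/dt`; `ylag(delta)`
#'   returns the full state vector at `t - delta` for any declared delay (or
#'   0, which yields the current stage state).
#' @param delays Numeric vector of delays (ms) that `rhs` may request.
#' @param history Initial history on `[-delta_max, 0]`: either a numeric
#'   vector (constant history) or a function of time returning the state.
#' @param config An [integratorConfig()].
#' @param nVars Number of state variables.
#' @param aux Initial auxiliary value passed to `rhs` and `postStep`.
#' @param postStep Optional `function(t, y, aux)` returning
#'   `list(y = ..., aux = ...)`, applied after each step.
#' @return List of class `ddeSolution` with `times` (0..duration) and `states`
#'   (matrix, one row per grid point).
#' @examples
#' # scalar exponential decay, no delay
#' sol <- integrateDDE(function(t, y, ylag, aux) -y, delays = 0,
#'                     history = 1, config = integratorConfig(0.01, 10), nVars = 1)
#' tail(sol$states, 1)  # ~ exp(-10)
#' @export
integrateDDE <- function(rhs, delays, history, config, nVars,
                         aux = NULL, postStep = NULL) {
  stopifnot(inherits(config, "IntegratorConfig"))
  dt <- config$dt
  nsteps <- round(config$duration / dt)
  if (abs(nsteps * dt - config$duration) > 1e-6 * config$duration)
    stop("duration must be an integer multiple of dt")
  ks <- .delaySteps(delays, dt)
  kmax <- max(0L, ks)

  X <- matrix(NA_real_, nrow = kmax + nsteps + 1L, ncol = nVars)
  httimes <- seq(-kmax * dt, 0, by = dt)
  if (is.function(history)) {
    for (j in seq_along(httimes)) {
      v <- history(httimes[j])
      if (length(v) != nVars) stop("history function must return nVars values")
      X[j, ] <- v
    }
  } else {
    if (length(history) != nVars) stop("constant history must have nVars values")
    X[seq_len(kmax + 1L), ] <- matrix(history, kmax + 1L, nVars, byrow = TRUE)
  }

  # mutable stage context shared with the single lag closure
  env <- new.env(parent = emptyenv())
  env$r <- kmax + 1L      # row of the current step's base point
  env$off <- 0            # stage offset in steps: 0, 0.5 or 1
  env$ystage <- X[kmax + 1L, ]
  ylag <- function(delta) {
    if (delta == 0) return(env$ystage)
    m <- match(delta, delays)
    if (is.na(m)) stop(sprintf("delay %g ms was not declared to the integrator", delta))
    k <- ks[m]
    if (env$off == 0) X[env$r - k, ]
    else if (env$off == 1) X[env$r - k + 1L, ]
    else 0.5 * (X[env$r - k, ] + X[env$r - k + 1L, ])
  }

  half <- dt / 2
  for (i in seq_len(nsteps)) {
    r <- kmax + i
    t <- (i - 1L) * dt
    y <- X[r, ]
    env$r <- r
    env$off <- 0; env$ystage <- y
    k1 <- rhs(t, y, ylag, aux)
    env$off <- 0.5; env$ystage <- y + half * k1
    k2 <- rhs(t + half, env$ystage, ylag, aux)
    env$ystage <- y + half * k2
    k3 <- rhs(t + half, env$ystage, ylag, aux)
    env$off <- 1; env$ystage <- y + dt * k3
    k4 <- rhs(t + dt, env$ystage, ylag, aux)
    ynew <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (any(!is.finite(ynew)))
      stop(sprintf("integration produced non-finite values at t = %g ms", t + dt))
    if (!is.null(postStep)) {
      ps <- postStep(t + dt, ynew, aux)
      ynew <- ps$y
      aux <- ps$aux
    }
    X[r + 1L, ] <- ynew
  }

  structure(list(times = seq(0, by = dt, length.out = nsteps + 1L),
                 states = X[(kmax + 1L):(kmax + nsteps + 1L), , drop = FALSE],
                 dt = dt),
            class = "ddeSolution")
}
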