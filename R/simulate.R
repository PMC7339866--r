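#' Simulate the STN-GPe loop, optionally under closed-loop DBS
#'
#' Integrates the delayed firing-rate model with the fixed-step RK4 scheme of
#' [integrateDDE()]. Stimulation acts on the deviation from the equilibrium
#' operating point: `mu(t) = -theta(t) * (x1(t) - x1bar)` enters the STN
#' activation argument, with `x1bar` taken from [findEquilibrium()] at the
#' inputs' reference (initial mean) levels unless `xref` is supplied. The
#' adaptive gain `theta` is carried as a third, non-delayed state variable
#' and clamped at zero after every step.
#'
#' For the `adaptive_beta` controller the biomarker stream is computed at
#' 1 kHz: the STN deviation is passed through a causal Butterworth band-pass
#' filter sample by sample (filter state carried across steps) and the drive
#' is the peak-to-peak amplitude of the filtered signal over the trailing
#' window, zero until the window is first filled.
#'
#' @param p A [loopParams()] object.
#' @param u1,u2 Cortical and striatal [inputConstant()]-family signals
#'   (striatal default: constant 2 pulses/s).
#' @param controller A [controllerConfig()] (default: off).
#' @param duration Simulation span (ms).
#' @param dt Integration step (ms); all delays must be integer multiples.
#' @param history Initial history: `NULL` (constant at the equilibrium),
#'   a length-2 numeric `c(x1, x2)`, or a function of `t` (ms `<= 0`)
#'   returning `c(x1, x2)`.
#' @param xref Optional reference equilibrium `c(x1bar, x2bar)` for the
#'   controller; computed from the inputs when `NULL`.
#' @return A `Trajectory`: data frame with columns `t_ms`, `x1`, `x2`,
#'   `theta`, `mu`, `u1`, `u2`, plus attributes `dt`, `params`, `controller`,
#'   `xref`.
#' @examples
#' \donttest{
#' p <- loopPreset("endogenous")
#' tr <- simulateLoop(p, u1 = inputConstant(27), duration = 2000)
#' dominantFrequency(tr$x1, fs = 1000 / attr(tr, "dt"))
#' }
#' @export
simulateLoop <- function(p, u1, u2 = inputConstant(2),
                         controller = controllerOff(),
                         duration = 5000, dt = 0.1,
                         history = NULL, xref = NULL) {
  stopifnot(inherits(p, "LoopParams"), inherits(u1, "InputSignal"),
            inherits(u2, "InputSignal"), inherits(controller, "ControllerConfig"))
  u1f <- inputFunction(u1)
  u2f <- inputFunction(u2)

  if (is.null(xref)) {
    eq <- findEquilibrium(p, .inputReferenceLevel(u1), .inputReferenceLevel(u2))
    xref <- c(eq$x1, eq$x2)
  }

  # inlined overflow-safe activations
  amp1 <- p$S1$a * p$S1$M; k1 <- 4 / p$S1$M; o1 <- log((p$S1$M - p$S1$B) / p$S1$B)
  amp2 <- p$S2$a * p$S2$M; k2 <- 4 / p$S2$M; o2 <- log((p$S2$M - p$S2$B) / p$S2$B)
  c11 <- p$c11; c12 <- p$c12; c21 <- p$c21; c22 <- p$c22
  b1 <- p$b1; b2 <- p$b2; tau1 <- p$tau1; tau2 <- p$tau2
  d11 <- p$delta11; d12 <- p$delta12; d21 <- p$delta21; d22 <- p$delta22
  mode <- controller$mode
  tOn <- controller$tOnMs
  sigma <- controller$sigma; tauTh <- controller$tauTheta
  xr1 <- xref[1]
  useC11 <- c11 > 0

  rhs <- function(t, y, ylag, aux) {
    l12 <- ylag(d12); l21 <- ylag(d21); l22 <- ylag(d22)
    on <- mode != "off" && t >= tOn
    mu <- if (on) -y[3] * (y[1] - xr1) else 0
    a1 <- (if (useC11) c11 * ylag(d11)[1] else 0) - c12 * l12[2] + b1 * u1f(t) + mu
    a2 <- c21 * l21[1] - c22 * l22[2] - b2 * u2f(t)
    dth <- if (on && mode == "adaptive_abs")
      (abs(y[1] - xr1) - sigma * y[3]) / tauTh
    else if (on && mode == "adaptive_beta")
      (aux$drive - sigma * y[3]) / tauTh
    else 0
    c((-y[1] + amp1 * stats::plogis(k1 * a1 - o1)) / tau1,
      (-y[2] + amp2 * stats::plogis(k2 * a2 - o2)) / tau2,
      dth)
  }

  aux <- new.env(parent = emptyenv())
  postStep <- NULL
  if (mode == "adaptive_beta") {
    stride <- max(1L, round(1 / dt))          # biomarker stream at ~1 kHz
    fsB <- 1000 / (dt * stride)
    flt <- .designFilter(filterSpec("butterworth", order = controller$filterOrder,
                                    bandHz = controller$bandHz, fs = fsB))
    bcoef <- as.numeric(flt$b); acoef <- as.numeric(flt$a)
    nz <- max(length(acoef), length(bcoef)) - 1L
    aux$z <- numeric(nz)
    nwin <- round(controller$windowMs * fsB / 1000)
    aux$buf <- numeric(nwin); aux$pos <- 0L; aux$filled <- FALSE
    aux$count <- 0L; aux$drive <- 0
    bc1 <- bcoef[1]; bcr <- bcoef[-1]; acr <- acoef[-1]
    postStep <- function(t, y, aux) {
      y[3] <- max(0, y[3])
      aux$count <- aux$count + 1L
      if (aux$count %% stride == 0L) {
        xin <- y[1] - xr1
        yf <- bc1 * xin + aux$z[1]
        aux$z <- bcr * xin - acr * yf + c(aux$z[-1], 0)
        aux$pos <- aux$pos %% nwin + 1L
        aux$buf[aux$pos] <- yf
        if (!aux$filled && aux$pos == nwin) aux$filled <- TRUE
        aux$drive <- if (aux$filled) {
          r <- range(aux$buf); r[2] - r[1]
        } else 0
      }
      list(y = y, aux = aux)
    }
  } else if (mode %in% c("adaptive_abs", "proportional")) {
    postStep <- function(t, y, aux) {
      y[3] <- max(0, y[3])
      list(y = y, aux = aux)
    }
  }

  theta0 <- switch(mode, off = 0, proportional = controller$theta,
                   controller$theta0)
  hist3 <- if (is.null(history)) {
    c(xref, theta0)
  } else if (is.function(history)) {
    function(t) c(history(t), theta0)
  } else {
    stopifnot(length(history) == 2)
    c(history, theta0)
  }

  sol <- integrateDDE(rhs, delays = c(if (useC11) d11, d12, d21, d22),
                      history = hist3,
                      config = integratorConfig(dt, duration), nVars = 3,
                      aux = aux, postStep = postStep)

  t_ms <- sol$times
  x1 <- sol$states[, 1]; x2 <- sol$states[, 2]; theta <- sol$states[, 3]
  on <- (mode != "off") & (t_ms >= tOn)
  mu <- ifelse(on, -theta * (x1 - xr1), 0)
  tr <- data.frame(t_ms = t_ms, x1 = x1, x2 = x2, theta = theta, mu = mu,
                   u1 = u1f(t_ms), u2 = u2f(t_ms))
  class(tr) <- c("Trajectory", "data.frame")
  attr(tr, "dt") <- dt
  attr(tr, "params") <- p
  attr(tr, "controller") <- controller
  attr(tr, "xref") <- xref

  bnd <- 1e-6
  if (any(x1 < -bnd | x1 > amp1 + bnd) || any(x2 < -bnd | x2 > amp2 + bnd))
    warning("firing rates left the [0, a*M] band; check step size and inputs")
  tr
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("<Trajectory> %d samples, %g ms at dt = %g ms; controller: %s\n",
              nrow(x), x$t_ms[nrow(x)], attr(x, "dt"), attr(x, "controller")$mode))
  invisible(x)
}

#' @export
plot.Trajectory <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$t_ms, x$x1, type = "l", xlab = "t (ms)",
                 ylab = "rate (pulses/s)", col = "firebrick", ...)
  graphics::lines(x$t_ms, x$x2, col = "steelblue")
  graphics::legend("topright", c("STN x1", "GPe x2"), lty = 1,
                   col = c("firebrick", "steelblue"), bty = "n")
  graphics::plot(x$t_ms, x$theta, type = "l", xlab = "t (ms)", ylab = "theta")
  invisible(x)
}

#' Write a trajectory to delimited text
#'
#' One header line, full float precision, columns
#' `t_ms, x1, x2, theta, mu, u1, u2`.
#'
#' @param tr A `Trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeTrajectory <- function(tr, path) {
  stopifnot(inherits(tr, "Trajectory"))
  df <- as.data.frame(lapply(tr, function(v) sprintf("%.17g", v)))
  names(df) <- names(tr)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
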