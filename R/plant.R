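#' Surrogate stimulation plant parameters
#'
#' A deliberately simple synthetic stand-in for the closed-loop observable of
#' a detailed spiking network: the measured beta ARV responds to stimulation
#' current through a monotone saturating suppression curve,
#' \deqn{ARV(t) = bg(t) \cdot \left[ floor + \frac{1 - floor}{1 + (I_{eff}/I_{50})^h} \right] + noise,}
#' where `bg(t)` is the background beta ARV, and the effective current
#' `I_eff = I_DBS * Z_E(0) / Z_E(t)` scales inversely with the electrode
#' impedance, so impedance growth weakens a fixed current's effect. A
#' first-order lag with time constant `lagMs` models the finite speed of the
#' network's response.
#'
#' @param bgHigh,bgLow High/low background beta ARV levels (uV).
#' @param i50 Half-suppression stimulation current (mA).
#' @param hill Steepness of the suppression curve.
#' @param floorFrac Residual ARV fraction at saturating stimulation.
#' @param noiseSd Additive Gaussian measurement noise SD (uV), applied per
#'   biomarker epoch; default 5% of `bgHigh`.
#' @param zE0 Baseline electrode impedance (kOhm).
#' @param lagMs Response lag time constant (ms).
#' @return An object of class `PlantParams`.
#' @export
plantParams <- function(bgHigh = 0.5, bgLow = 0.08, i50 = 0.5, hill = 2,
                        floorFrac = 0.05, noiseSd = 0.05 * bgHigh,
                        zE0 = 0.5, lagMs = 100) {
  stopifnot(bgHigh > 0, bgLow >= 0, i50 > 0, hill > 0,
            floorFrac >= 0, floorFrac < 1, noiseSd >= 0, zE0 > 0, lagMs > 0)
  structure(list(bgHigh = bgHigh, bgLow = bgLow, i50 = i50, hill = hill,
                 floorFrac = floorFrac, noiseSd = noiseSd, zE0 = zE0,
                 lagMs = lagMs),
            class = "PlantParams")
}

# suppression multiplier in [floorFrac, 1], monotone non-increasing in ieff
.suppression <- function(params, ieff) {
  params$floorFrac + (1 - params$floorFrac) / (1 + (ieff / params$i50)^params$hill)
}

#' One internal step of the surrogate plant
#'
#' Advances the lagged ARV state by `dt` under stimulation current `iDbs`
#' (noise-free; measurement noise is added at the biomarker epoch level by
#' [runScenario()]).
#'
#' @param state Current lagged ARV (uV); use `NULL` to initialize at the
#'   instantaneous target of the suppression curve.
#' @param iDbs Stimulation current (mA, `>= 0`).
#' @param params [plantParams()].
#' @param background Background beta ARV at this instant (uV).
#' @param zE Electrode impedance at this instant (kOhm).
#' @param dt Step (ms).
#' @return Updated lagged ARV (uV).
#' @export
plantStep <- function(state, iDbs, params, background, zE, dt = 1) {
  stopifnot(inherits(params, "PlantParams"), iDbs >= 0, zE > 0)
  ieff <- iDbs * params$zE0 / zE
  tgt <- background * .suppression(params, ieff)
  if (is.null(state)) return(tgt)
  al <- exp(-dt / params$lagMs)     # exact first-order lag update
  al * state + (1 - al) * tgt
}

#' Scenario schedules for the surrogate plant
#'
#' Piecewise-in-time schedules for the three clinical-style adaptation
#' scenarios, each 130 s long:
#' \describe{
#'   \item{`target_variation`}{background beta high throughout; target
#'     10, 0.2, 0.05, 0.15, 10 uV over 0-10, 10-40, 40-70, 70-100,
#'     100-130 s.}
#'   \item{`beta_variation`}{target fixed at 0.1 uV; background low on
#'     0-10, 40-70, 100-130 s and high on 10-40, 70-100 s.}
#'   \item{`impedance_variation`}{target 0.1 uV and background high
#'     throughout; impedance 0.5 kOhm up to 30 s then ramped linearly to
#'     2.5 kOhm at 130 s.}
#' }
#'
#' @param name Scenario name.
#' @param params [plantParams()] supplying the background levels.
#' @param durationS Duration (s), default 130.
#' @return An object of class `ScenarioSpec` with fields `name`, `durationS`
#'   and vectorized schedule functions `target(t_s)`, `background(t_s)`,
#'   `impedance(t_s)`.
#' @export
scenarioSpec <- function(name = c("target_variation", "beta_variation",
                                  "impedance_variation"),
                         params = plantParams(), durationS = 130) {
  name <- match.arg(name)
  stopifnot(inherits(params, "PlantParams"), durationS > 0)
  hi <- params$bgHigh; lo <- params$bgLow; z0 <- params$zE0
  pw <- function(breaks, levels) {
    force(breaks); force(levels)
    function(t) levels[findInterval(t, breaks) + 1L]
  }
  sc <- switch(name,
    target_variation = list(
      target = pw(c(10, 40, 70, 100), c(10, 0.2, 0.05, 0.15, 10)),
      background = function(t) rep_len(hi, length(t)),
      impedance = function(t) rep_len(z0, length(t))),
    beta_variation = list(
      target = function(t) rep_len(0.1, length(t)),
      background = pw(c(10, 40, 70, 100), c(lo, hi, lo, hi, lo)),
      impedance = function(t) rep_len(z0, length(t))),
    impedance_variation = list(
      target = function(t) rep_len(0.1, length(t)),
      background = function(t) rep_len(hi, length(t)),
      impedance = function(t) pmin(z0 + pmax(t - 30, 0) * (2.5 - z0) / 100, 2.5)))
  structure(c(list(name = name, durationS = durationS, params = params), sc),
            class = "ScenarioSpec")
}

#' Run a closed-loop scenario on the surrogate plant
#'
#' Simulates the plant at a 1 ms internal step for the scenario's duration.
#' The biomarker is measured once per non-overlapping 100 ms epoch (the mean
#' lagged ARV over the epoch plus seeded Gaussian noise) and the controller
#' updates once per completed epoch: for the self-tuning law the gain
#' integrates the half-wave-rectified normalized tracking error with
#' sigma-modification leakage, and the stimulation current is positive
#' feedback on the biomarker, `I_DBS = theta * ARV`.
#'
#' The tracking error entering both the gain law and the reported MSE is
#' normalized by the target. The MSE is expressed as a percentage of the
#' stimulation-off MSE for the same scenario and seed.
#'
#' @param spec A [scenarioSpec()].
#' @param controller A [controllerConfig()] with mode `"off"`,
#'   `"proportional"` (positive-feedback fixed gain) or `"adaptive_arv"`.
#' @param params [plantParams()]; defaults to those carried by the scenario.
#' @param seed RNG seed for the measurement noise.
#' @param epochMs Biomarker epoch (ms).
#' @return List of class `ScenarioRun`: `traces` (data frame `t_s, target,
#'   arv, idbs_ma, theta, ze_kohm` at epoch cadence) and `report` (list
#'   `mse`, `msePct`, `powerUw`).
#' @export
runScenario <- function(spec, controller, params = NULL, seed = 1,
                        epochMs = 100) {
  stopifnot(inherits(spec, "ScenarioSpec"), inherits(controller, "ControllerConfig"))
  if (!controller$mode %in% c("off", "proportional", "adaptive_arv"))
    stop("plant scenarios support modes off, proportional and adaptive_arv")
  if (is.null(params)) params <- spec$params
  dtMs <- 1
  nPerEpoch <- round(epochMs / dtMs)
  nEpoch <- floor(spec$durationS * 1000 / epochMs)

  # The 1 ms lag recursion s_j = al*s_{j-1} + (1-al)*tgt has, for the constant
  # within-epoch stimulation, the exact epoch summary used below (final state
  # and epoch-mean in closed form) -- identical to stepping plantStep() at
  # dtMs but without the inner loop.
  al <- exp(-dtMs / params$lagMs)
  aln <- al^nPerEpoch
  geo <- al * (1 - aln) / (nPerEpoch * (1 - al))

  run <- function(mode, seed) {
    set.seed(seed)
    theta <- switch(mode, off = 0, proportional = controller$theta,
                    controller$theta0)
    iDbs <- 0
    state <- NULL
    out <- matrix(NA_real_, nEpoch, 6)
    for (ep in seq_len(nEpoch)) {
      tMid <- ((ep - 1) + 0.5) * epochMs / 1000
      ieff <- iDbs * params$zE0 / spec$impedance(tMid)
      tgtArv <- spec$background(tMid) * .suppression(params, ieff)
      if (is.null(state)) state <- tgtArv
      meanArv <- tgtArv + (state - tgtArv) * geo
      state <- aln * state + (1 - aln) * tgtArv
      tS <- ep * nPerEpoch * dtMs / 1000
      biomarker <- max(0, meanArv + stats::rnorm(1, 0, params$noiseSd))
      target <- spec$target(tS)
      if (mode == "adaptive_arv" && tS * 1000 >= controller$tOnMs) {
        drive <- errorDrive(biomarker, target, normalized = TRUE)
        theta <- adaptiveGainStep(theta, drive, controller$sigma,
                                  controller$tauTheta, epochMs)
      }
      iDbs <- if (mode == "off" || tS * 1000 < controller$tOnMs) 0
              else theta * biomarker
      out[ep, ] <- c(tS, target, biomarker, iDbs, theta, spec$impedance(tS))
    }
    colnames(out) <- c("t_s", "target", "arv", "idbs_ma", "theta", "ze_kohm")
    as.data.frame(out)
  }

  tr <- run(controller$mode, seed)
  dtS <- epochMs / 1000
  e <- (tr$arv - tr$target) / tr$target
  mseVal <- meanSquaredError(e, dtS)
  pc <- powerConsumption(tr$idbs_ma, tr$ze_kohm, dtS)
  trOff <- if (controller$mode == "off") tr else run("off", seed)
  eOff <- (trOff$arv - trOff$target) / trOff$target
  mseOff <- meanSquaredError(eOff, dtS)
  structure(list(traces = tr,
                 report = list(mse = mseVal, msePct = 100 * mseVal / mseOff,
                               powerUw = pc)),
            class = "ScenarioRun")
}

#' @export
print.ScenarioRun <- function(x, ...) {
  cat(sprintf("<ScenarioRun> MSE = %.1f%% of stimulation-off, power = %.1f uW\n",
              x$report$msePct, x$report$powerUw))
  invisible(x)
}

#' Write a scenario performance report
#'
#' Emits a performance table (controller label, MSE as % of stimulation-off,
#' power in uW) as CSV, and optionally the same content as JSON.
#'
#' @param runs Named list of `ScenarioRun` objects (names = controller labels).
#' @param csvPath,jsonPath Output paths (`NULL` to skip).
#' @return The report data frame, invisibly.
#' @export
writePerformanceReport <- function(runs, csvPath = NULL, jsonPath = NULL) {
  df <- data.frame(
    controller = names(runs),
    mse_pct = vapply(runs, function(r) r$report$msePct, numeric(1)),
    power_uw = vapply(runs, function(r) r$report$powerUw, numeric(1)),
    row.names = NULL)
  if (!is.null(csvPath)) utils::write.csv(df, csvPath, row.names = FALSE)
  if (!is.null(jsonPath))
    jsonlite::write_json(df, jsonPath, dataframe = "rows", digits = NA)
  invisible(df)
}
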