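#' Read a run configuration file
#'
#' Structured text configuration (YAML, or JSON by file extension) whose keys
#' mirror the constructor arguments of the addressed engine. Every file has a
#' top-level `command` (one of `simulate`, `sweep`, `bode`, `identify`,
#' `scenario`) plus command-specific sections; see the packaged examples
#' under `system.file("extdata", package = "betadbs")`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list with class `RunConfig`.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
  if (is.null(cfg$command))
    stop("config must declare a top-level 'command'")
  cfg$command <- match.arg(cfg$command,
                           c("simulate", "sweep", "bode", "identify", "scenario"))
  cfg$.path <- path
  class(cfg) <- "RunConfig"
  cfg
}

.cfgLoopParams <- function(m) {
  if (is.null(m)) stop("config section 'model' is required")
  if (!is.null(m$preset)) return(loopPreset(m$preset))
  req <- c("c12", "c21", "c22", "b1", "b2")
  miss <- setdiff(req, names(m))
  if (length(miss)) stop(sprintf("model config missing fields: %s",
                                 paste(miss, collapse = ", ")))
  do.call(loopParams, m[intersect(names(m), names(formals(loopParams)))])
}

.cfgInput <- function(s, default) {
  if (is.null(s)) return(default)
  switch(match.arg(s$kind, c("constant", "sinusoid", "piecewise")),
    constant = inputConstant(s$level),
    sinusoid = inputSinusoid(s$freq_hz, s$mean, s$amplitude,
                             switchMs = s$switch_ms,
                             meanAfter = s$mean_after %||% s$mean,
                             amplitudeAfter = s$amplitude_after %||% s$amplitude),
    piecewise = inputPiecewise(s$breaks_ms, s$levels))
}

.cfgController <- function(s) {
  if (is.null(s)) return(controllerOff())
  mode <- match.arg(s$mode, c("off", "proportional", "adaptive_abs",
                              "adaptive_beta", "adaptive_arv"))
  controllerConfig(mode,
                   theta = s$theta %||% 0,
                   theta0 = s$theta0 %||% 0,
                   tauTheta = s$tau_theta_ms %||% 75,
                   sigma = s$sigma %||% 0.19,
                   target = s$target %||% 0,
                   tOnMs = s$t_on_ms %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Execute a configured command and write its artifacts
#'
#' Dispatches on the config's `command`, runs the corresponding engine and
#' writes its CSV/JSON artifacts into `outDir` together with a
#' `manifest.json` echoing the resolved configuration, the seed and the MD5
#' of the input config file, so deterministic runs are exactly reproducible.
#'
#' @param cfg A [readRunConfig()] object (or a path to one).
#' @param outDir Output directory (created if needed).
#' @param seed Integer seed recorded in the manifest and used for every
#'   stochastic command.
#' @param quiet Suppress progress messages (messages go to stderr; numeric
#'   outputs never do).
#' @return Invisible character vector of the artifact paths written.
#' @export
runCommand <- function(cfg, outDir, seed = 1, quiet = FALSE) {
  if (is.character(cfg)) cfg <- readRunConfig(cfg)
  stopifnot(inherits(cfg, "RunConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  arts <- character(0)
  emit <- function(name) {
    p <- file.path(outDir, name)
    arts <<- c(arts, p)
    p
  }
  set.seed(seed)

  if (cfg$command == "simulate") {
    p <- .cfgLoopParams(cfg$model)
    tr <- simulateLoop(p,
                       u1 = .cfgInput(cfg$u1, inputConstant(27)),
                       u2 = .cfgInput(cfg$u2, inputConstant(2)),
                       controller = .cfgController(cfg$controller),
                       duration = cfg$duration_ms %||% 2000,
                       dt = cfg$dt_ms %||% 0.1)
    writeTrajectory(tr, emit("trajectory.csv"))
    say("simulate: wrote %d samples", nrow(tr))
  } else if (cfg$command == "sweep") {
    p <- .cfgLoopParams(cfg$model)
    res <- oscillationMap(p, c12Values = cfg$c12_values,
                          c21Values = cfg$c21_values,
                          u1bar = cfg$u1_level %||% 27,
                          u2bar = cfg$u2_level %||% 2,
                          duration = cfg$duration_ms %||% 5000,
                          steadyMs = cfg$steady_ms %||%
                            min(2000, (cfg$duration_ms %||% 5000) / 2),
                          dt = cfg$dt_ms %||% 0.1)
    utils::write.csv(as.data.frame(res), emit("oscillation_map.csv"),
                     row.names = FALSE)
    say("sweep: %d cells", length(cfg$c12_values) * length(cfg$c21_values))
  } else if (cfg$command == "bode") {
    p <- .cfgLoopParams(cfg$model)
    res <- bodeProfile(p, freqsHz = cfg$freqs_hz,
                       inputMean = cfg$input_mean,
                       inputAmplitude = cfg$input_amplitude,
                       controller = if (is.null(cfg$controller)) NULL
                                    else .cfgController(cfg$controller),
                       dt = cfg$dt_ms %||% 0.1)
    utils::write.csv(as.data.frame(res), emit("bode_profile.csv"),
                     row.names = FALSE)
    say("bode: %d frequencies", length(cfg$freqs_hz))
  } else if (cfg$command == "identify") {
    # two-stage procedure: the activation is fitted on pairs measured with
    # the GPe self-coupling removed, then c22 is estimated on pairs measured
    # with the coupling present
    if (!is.null(cfg$pairs_csv)) {
      d0 <- utils::read.csv(file.path(dirname(cfg$.path), cfg$pairs_free_csv))
      pairs0 <- ratePairs(d0[[1]], d0[[2]])
      d <- utils::read.csv(file.path(dirname(cfg$.path), cfg$pairs_csv))
      pairs <- ratePairs(d[[1]], d[[2]])
    } else {
      s <- cfg$synthetic
      truth <- activationParams(s$M, s$B, s$a %||% 1)
      pairs0 <- generateRatePairs(truth, c22 = 0, n = s$n_pairs %||% 50,
                                  uRange = c(s$u_min %||% 0, s$u_max %||% 250),
                                  noiseSd = s$noise_sd %||% 0, seed = seed)
      pairs <- generateRatePairs(truth, c22 = s$c22, n = s$n_pairs %||% 50,
                                 uRange = c(s$u_min %||% 0, s$u_max %||% 250),
                                 noiseSd = s$noise_sd %||% 0, seed = seed + 1)
    }
    fit <- fitActivation(pairs0)
    est <- estimateC22(fit$params, pairs)
    l2 <- activationMaxSlope(fit$params)
    out <- list(a = fit$a, M = fit$params$M, B = fit$params$B,
                c22 = est$c22, nlsq = est$nlsq, l2 = l2,
                stabilizable = stabilizabilityCheck(est$c22, l2)$satisfied)
    jsonlite::write_json(out, emit("identification.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(as.data.frame(pairs), emit("rate_pairs.csv"),
                     row.names = FALSE)
    say("identify: c22 = %.3f (nLSQ %.2e)", est$c22, est$nlsq)
  } else if (cfg$command == "scenario") {
    params <- do.call(plantParams, cfg$plant %||% list())
    spec <- scenarioSpec(cfg$scenario %||% "target_variation", params = params)
    ctrl <- .cfgController(cfg$controller %||%
                             list(mode = "adaptive_arv", target = 0.1,
                                  tau_theta_ms = 100, sigma = 0.00875))
    runres <- runScenario(spec, ctrl, params = params, seed = seed)
    utils::write.csv(runres$traces, emit("scenario_traces.csv"),
                     row.names = FALSE)
    jsonlite::write_json(runres$report, emit("scenario_report.json"),
                         auto_unbox = TRUE, digits = NA)
    say("scenario %s: MSE %.1f%%, power %.1f uW", spec$name,
        runres$report$msePct, runres$report$powerUw)
  }

  manifest <- list(command = cfg$command, seed = seed,
                   config = unclass(cfg)[setdiff(names(cfg), ".path")],
                   config_md5 = unname(tools::md5sum(cfg$.path)),
                   artifacts = basename(arts),
                   package_version = as.character(utils::packageVersion("betadbs")))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(arts, file.path(outDir, "manifest.json")))
}
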