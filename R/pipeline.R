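# Orchestration of the two analysis workflows: transition-path fitting
# (calibration -> surfaces -> pooled estimate -> bootstrap) and
# barrier-shape inference (per-transition histogram -> candidate scan).

#' Configuration for the orchestrated pipelines
#'
#' @param cohort either a [simulationConfig()] (synthetic cohort) or a list
#'   of [TransitionWindow-class] objects (measured/loaded windows).
#' @param tauGrid,eGrid analysis grids.
#' @param slowRates fixed slow model rates.
#' @param nBootstrap bootstrap trials for the pooled estimate.
#' @param seed integer seed controlling simulation and bootstrap.
#' @param outputDir optional directory for artifacts (CSV/JSON); `NULL`
#'   keeps everything in memory.
#' @param candidates,nRep,scaleGrid shape-inference settings (see
#'   [barrierShapeScan()]).
#' @return list of class `tpfretPipelineConfig`.
#' @export
pipelineConfig <- function(cohort, tauGrid = defaultTauGrid(),
                           eGrid = defaultEGrid(),
                           slowRates = defaultSlowRates(),
                           nBootstrap = 1000, seed = 1, outputDir = NULL,
                           candidates = NULL, nRep = 27,
                           scaleGrid = seq(0.9, 1.3, by = 0.05)) {
  structure(list(cohort = cohort, tauGrid = tauGrid, eGrid = eGrid,
                 slowRates = slowRates, nBootstrap = nBootstrap,
                 seed = seed, outputDir = outputDir,
                 candidates = candidates, nRep = nRep,
                 scaleGrid = scaleGrid),
            class = "tpfretPipelineConfig")
}

.getWindows <- function(config) {
  if (inherits(config$cohort, "tpfretSimConfig")) {
    set.seed(config$seed)
    simulateTransitionCohort(config$cohort)$windows
  } else config$cohort
}

#' Run the transition-path fitting pipeline
#'
#' Calibrates every window from its own state rates, computes the
#' per-window log-likelihood difference surfaces, pools them, and
#' bootstraps the standard errors of the pooled mean transition-path time
#' and intermediate efficiency.  Deterministic given the configured seed.
#'
#' @param config a [pipelineConfig()].
#' @return list (report bundle): `tTP`, `eHat`, `seTau`, `seE`,
#'   `nTransitions`, `pooled` (a [LikelihoodSurface-class]), `surfaces`,
#'   `windows`, `calibrations`, `provenance`.
#' @export
runTransitionPipeline <- function(config) {
  stopifnot(inherits(config, "tpfretPipelineConfig"))
  windows <- .getWindows(config)
  if (!length(windows)) stop("calibration stage: no analyzable windows")
  calibs <- lapply(windows, function(w) {
    cal <- try(calibrateWindow(w), silent = TRUE)
    if (inherits(cal, "try-error"))
      stop("calibration stage failed for window ", w@photons@traceId, ": ",
           attr(cal, "condition")$message)
    cal
  })
  surfaces <- vector("list", length(windows))
  for (j in seq_along(windows))
    surfaces[[j]] <- deltaLnLSurface(windows[[j]], calibs[[j]],
                                     tauGrid = config$tauGrid,
                                     eGrid = config$eGrid,
                                     slowRates = config$slowRates)
  pooled <- poolSurfaces(surfaces)
  boot <- bootstrapSE(surfaces, nTrials = config$nBootstrap,
                      seed = config$seed + 1L)
  report <- list(tTP = pooled@tauHat, eHat = pooled@eHat,
                 seTau = boot$seTau, seE = boot$seE,
                 nTransitions = length(windows), pooled = pooled,
                 surfaces = surfaces, windows = windows,
                 calibrations = calibs,
                 provenance = list(seed = config$seed,
                                   nBootstrap = config$nBootstrap,
                                   tauGridRange = range(config$tauGrid),
                                   eGridRange = range(config$eGrid)))
  if (!is.null(config$outputDir)) {
    dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
    writeSurfaceCSV(pooled, file.path(config$outputDir, "pooled_surface.csv"))
    jsonlite::write_json(
      list(tTP_us = pooled@tauHat * 1e6, E_hat = pooled@eHat,
           se_tau_us = boot$seTau * 1e6, se_E = boot$seE,
           n_transitions = length(windows), seed = config$seed),
      file.path(config$outputDir, "transition_report.json"),
      auto_unbox = TRUE, digits = NA)
  }
  report
}

#' Run the barrier-shape inference pipeline
#'
#' Computes per-transition lifetime estimates at the pooled efficiency,
#' histograms them, and scans the candidate barrier-shape library.
#'
#' @param config a [pipelineConfig()] with a `candidates` list.
#' @param transitionReport output of [runTransitionPipeline()].
#' @param edges histogram edges.
#' @return list: `scan` (a [ShapeScanResult-class]), `hist`
#'   (a [TauHistogram-class]), `fits`, plus the measured summary.
#' @export
runShapeInference <- function(config, transitionReport,
                              edges = defaultTauEdges()) {
  stopifnot(inherits(config, "tpfretPipelineConfig"))
  if (is.null(config$candidates))
    stop("shape-inference stage: no candidate library configured")
  an <- cohortTauAnalysis(transitionReport$windows, transitionReport$eHat,
                          tauGrid = config$tauGrid,
                          slowRates = config$slowRates)
  h <- tauHistogram(an$fits$tauHatJ, an$fits$hasMaximum, edges)
  simCfg <- if (inherits(config$cohort, "tpfretSimConfig")) config$cohort
            else simulationConfig(nTransitions = length(transitionReport$windows))
  simCfg$nTransitions <- length(transitionReport$windows)
  set.seed(config$seed + 2L)
  scan <- barrierShapeScan(
    list(hist = h, tTP = transitionReport$tTP, eHat = transitionReport$eHat),
    config$candidates, simCfg, nRep = config$nRep,
    scaleGrid = config$scaleGrid, tauGrid = config$tauGrid)
  if (!is.null(config$outputDir)) {
    dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
    writeHistogramCSV(h, file.path(config$outputDir, "tau_histogram.csv"))
    write.table(scan@table, file.path(config$outputDir, "shape_scan.csv"),
                sep = ",", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(best_candidate = scan@bestCandidate, seed = config$seed),
      file.path(config$outputDir, "shape_report.json"),
      auto_unbox = TRUE, digits = NA)
  }
  list(scan = scan, hist = h, fits = an$fits, tTP = transitionReport$tTP,
       eHat = transitionReport$eHat)
}
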