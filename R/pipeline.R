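# End-to-end pipeline: simulate (or load) -> extract -> angles -> indices
# -> onset -> kinetic fits, with plain CSV/JSON artifacts so that every
# stage is auditable and re-runnable, and bit-stable outputs under a fixed
# seed.

scenarioAsList <- function(config) {
  out <- lapply(methods::slotNames(config), function(s) {
    v <- methods::slot(config, s)
    if (is(v, "AsymptoticParams")) as.list(theta(v)) else v
  })
  stats::setNames(out, methods::slotNames(config))
}

stageRun <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full thermal stress-analysis pipeline
#'
#' Orchestrates the stages simulate (or load) -> temperature extraction ->
#' leaf angles -> stress indices -> wilting onset -> asymptotic kinetic
#' fits, writing plain CSV/JSON artifacts into `outDir`. The same
#' configuration and seed reproduce every output byte for byte.
#'
#' @param scenario a [ScenarioConfig-class] to simulate, or `NULL` when
#'   loading from a manifest. Exactly one of `scenario` and `manifest`
#'   must be supplied.
#' @param manifest path to a sequence manifest CSV (see [readSequence()]).
#' @param roiConfig ROI configuration path, required with `manifest`.
#' @param schedule day/night schedule: data.frame with `lightsOnMin`,
#'   `lightsOffMin`, or a CSV path; required with `manifest`.
#' @param outDir output directory, created if needed.
#' @param seed optional integer overriding the scenario's seed.
#' @param refs optional index reference list (`tNws`, `tMax`, `tDry`,
#'   `tWet`); derived from the series via [referencesFromSeries()] when
#'   `NULL`.
#' @param G optional stomatal-conductance calibration constant, m/s per Ig.
#' @param onset `"auto"` to detect per plant, or a numeric onset time in
#'   minutes applied to all plants.
#' @param fitHorizonHours length of the post-onset fitting window, hours.
#' @param fitBinMin width of the time bins averaged before fitting,
#'   minutes.
#' @param switchMargin,hysteresisMin passed to [assignLeafTemperature()].
#' @param segThreshold passed to [measureAngles()].
#' @param writeFrames also write every frame (plus manifest and ROI
#'   config) under `outDir/frames`.
#' @return invisibly, a list with `series`, `angles`, `indices`, `onsets`
#'   (named minutes), `fits` (named list of [StressKineticsFit-class]),
#'   `report` (the run report) and `files` (paths written).
#' @examples
#' \donttest{
#' cfg <- scenarioConfig(nDays = 3, cadence = 60, frameShape = c(60, 80),
#'                       leafLength = 16, leafWidth = 5, noiseSd = 0)
#' res <- runPipeline(scenario = cfg, outDir = tempfile("run"))
#' res$onsets
#' }
#' @export
runPipeline <- function(scenario = NULL, manifest = NULL, roiConfig = NULL,
                        schedule = NULL, outDir, seed = NULL, refs = NULL,
                        G = NULL, onset = "auto", fitHorizonHours = 8,
                        fitBinMin = 30, switchMargin = 0.5,
                        hysteresisMin = 60, segThreshold = 0.8,
                        writeFrames = FALSE) {
  if (is.null(scenario) == is.null(manifest))
    stop("supply exactly one of 'scenario' and 'manifest'")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logFile <- file.path(outDir, "run.log")
  logLines <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    logLines <<- c(logLines, msg)
    message(msg)
  }

  if (!is.null(scenario)) {
    if (!is.null(seed)) scenario@seed <- as.numeric(seed)
    note("simulate: generating scenario (seed %g)", scenario@seed)
    gen <- stageRun("simulate", generateSequence(scenario))
    sequence <- gen$sequence
    if (writeFrames)
      stageRun("simulate", writeSequence(sequence, file.path(outDir, "frames")))
    inputDesc <- list(mode = "simulation", scenario = scenarioAsList(scenario))
  } else {
    if (is.null(roiConfig))
      stop("a manifest run requires an ROI configuration")
    if (is.character(schedule)) schedule <- utils::read.csv(schedule)
    note("load: reading sequence from %s", manifest)
    sequence <- stageRun("load",
                         readSequence(manifest, roiConfig,
                                      dayNightSchedule = schedule))
    inputDesc <- list(mode = "manifest", manifest = manifest,
                      roiConfig = roiConfig)
  }
  sched <- daySchedule(sequence)

  note("extract: ROI temperatures for %d frames", length(sequence))
  assigned <- stageRun("extract",
                       assignLeafTemperature(extractReadings(sequence),
                                             switchMargin, hysteresisMin))
  note("angles: segmenting and measuring leaf angles")
  angles <- stageRun("angles", measureAngles(sequence, segThreshold))
  series <- plantTimeSeries(assigned, angles)

  plants <- unique(series$plant)
  onsets <- stats::setNames(rep(NA_real_, length(plants)), plants)
  if (identical(onset, "auto")) {
    for (p in plants) {
      res <- stageRun(paste0("onset:", p),
                      detectWiltingOnset(series[series$plant == p, ],
                                         schedule = sched))
      onsets[p] <- onsetTime(res)
    }
  } else {
    onsets[] <- as.numeric(onset)
  }
  anchor <- if (all(is.na(onsets))) NA_real_ else min(onsets, na.rm = TRUE)
  note("onset: anchor at %s min", format(anchor))

  fits <- list()
  if (!is.na(anchor)) {
    for (p in plants) {
      sp <- series[series$plant == p &
                     series$time >= anchor &
                     series$time <= anchor + fitHorizonHours * 60, ]
      if (nrow(sp) < 5L) next
      bin <- floor((sp$time - anchor) / fitBinMin)
      xs <- tapply(sp$time, bin, mean) - anchor
      ys <- tapply(sp$leafTemp, bin, mean)
      fits[[p]] <- stageRun(
        paste0("fit:", p),
        fitAsymptotic(as.numeric(xs) / 60, as.numeric(ys),
                      horizon = fitHorizonHours))
      note("fit %s: theta = (%.3f, %.3f, %.4f), %s", p,
           theta(fits[[p]])[1], theta(fits[[p]])[2], theta(fits[[p]])[3],
           shapeClass(fits[[p]]))
    }
  }

  if (is.null(refs))
    refs <- stageRun("indices", referencesFromSeries(series, sched))
  indices <- stageRun("indices", indexTable(series, refs, G))

  files <- list(series = file.path(outDir, "series.csv"),
                angles = file.path(outDir, "angles.csv"),
                indices = file.path(outDir, "indices.csv"),
                report = file.path(outDir, "run_report.json"))
  utils::write.csv(series, files$series, row.names = FALSE, quote = FALSE)
  utils::write.csv(angles, files$angles, row.names = FALSE, quote = FALSE)
  utils::write.csv(indices, files$indices, row.names = FALSE, quote = FALSE)
  for (p in names(fits)) {
    f <- fits[[p]]
    files[[paste0("fit_", p)]] <- file.path(outDir,
                                            sprintf("fit_%s.json", p))
    jsonlite::write_json(
      list(plant = p, theta = as.list(theta(f)),
           se = as.list(f@se), rss = f@rss, converged = f@converged,
           nIter = f@nIter, shapeClass = shapeClass(f),
           predictedEquilibrium = predictedEquilibrium(f),
           conditioningWarning = f@conditioningWarning,
           residualDiagnostics = f@residualDiagnostics,
           tolerances = list(rssTol = 1e-10, gradTol = 1e-8,
                             maxIter = 500)),
      files[[paste0("fit_", p)]], auto_unbox = TRUE, digits = NA)
  }

  report <- list(
    package = "thermoleaf",
    version = as.character(utils::packageVersion("thermoleaf")),
    input = inputDesc,
    parameters = list(switchMargin = switchMargin,
                      hysteresisMin = hysteresisMin,
                      segThreshold = segThreshold,
                      fitHorizonHours = fitHorizonHours,
                      fitBinMin = fitBinMin,
                      lowessSpan = 0.5,
                      onsetRateThreshold = 15, onsetSustainMin = 30),
    references = refs,
    onsets = as.list(onsets),
    files = lapply(files, basename))
  jsonlite::write_json(report, files$report, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  writeLines(logLines, logFile)

  invisible(list(series = series, angles = angles, indices = indices,
                 onsets = onsets, fits = fits, report = report,
                 files = files))
}
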