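#' @rdname ThermalFrame-class
#' @export
setMethod("temperatures", "ThermalFrame", function(x) x@temperatures)

#' @rdname ThermalFrame-class
#' @export
setMethod("timestamp", "ThermalFrame", function(x) x@timestamp)

#' @rdname ThermalFrame-class
#' @export
setMethod("emissivity", "ThermalFrame", function(x) x@emissivity)

#' @rdname ThermalFrame-class
#' @export
setMethod("frameId", "ThermalFrame", function(x) x@frameId)

#' @rdname FrameSequence-class
#' @export
setMethod("frames", "FrameSequence", function(x) x@frames)

#' @rdname FrameSequence-class
#' @export
setMethod("rois", "FrameSequence", function(x) x@rois)

#' @rdname FrameSequence-class
#' @export
setMethod("cadence", "FrameSequence", function(x) x@cadence)

#' @rdname FrameSequence-class
#' @export
setMethod("daySchedule", "FrameSequence", function(x) x@dayNightSchedule)

#' @rdname FrameSequence-class
#' @param i frame index
#' @export
setMethod("[[", "FrameSequence", function(x, i) x@frames[[i]])

#' @rdname FrameSequence-class
#' @export
setMethod("length", "FrameSequence", function(x) length(x@frames))

#' @rdname AsymptoticParams-class
#' @export
setMethod("theta", "AsymptoticParams", function(x)
  c(theta1 = x@theta1, theta2 = x@theta2, theta3 = x@theta3))

#' @rdname AsymptoticParams-class
#' @export
setMethod("theta", "StressKineticsFit", function(x) theta(x@params))

#' @rdname predictedEquilibrium
#' @export
setMethod("predictedEquilibrium", "StressKineticsFit",
          function(x) x@params@theta1)

#' @rdname StressKineticsFit-class
#' @export
setMethod("converged", "StressKineticsFit", function(x) x@converged)

#' @rdname StressKineticsFit-class
#' @export
setMethod("shapeClass", "StressKineticsFit", function(x) x@shapeClass)

#' @rdname OnsetResult-class
#' @export
setMethod("onsetTime", "OnsetResult", function(x) x@onsetTime)

setMethod("show", "ThermalFrame", function(object) {
  d <- dim(object@temperatures)
  cat(sprintf("ThermalFrame '%s': %d x %d px, t = %g min, emissivity %.2f\n",
              object@frameId, d[1], d[2], object@timestamp,
              object@emissivity))
  cat(sprintf("  temperature range: %.2f - %.2f degC\n",
              min(object@temperatures), max(object@temperatures)))
})

setMethod("show", "RegionOfInterest", function(object) {
  cat(sprintf("RegionOfInterest '%s' (%s, %s): rows [%g, %g), cols [%g, %g)\n",
              object@name, object@shape, object@role,
              object@bounds[1], object@bounds[3],
              object@bounds[2], object@bounds[4]))
})

setMethod("show", "FrameSequence", function(object) {
  n <- length(object@frames)
  ts <- vapply(object@frames, function(f) f@timestamp, numeric(1))
  d <- dim(object@frames[[1]]@temperatures)
  cat(sprintf("FrameSequence: %d frames of %d x %d px, %g-min cadence, t = %g..%g min\n",
              n, d[1], d[2], object@cadence, min(ts), max(ts)))
  cat(sprintf("  %d ROI(s), %d scheduled day(s)\n",
              length(object@rois), nrow(object@dayNightSchedule)))
})

setMethod("show", "AsymptoticParams", function(object) {
  cat(sprintf(
    "AsymptoticParams: Y = %.4g - %.4g * exp(-%.4g * X)  (residual sd %.3g)\n",
    object@theta1, object@theta2, object@theta3, object@residualSd))
})

setMethod("show", "StressKineticsFit", function(object) {
  p <- theta(object)
  cat("StressKineticsFit (asymptotic model Y = theta1 - theta2*exp(-theta3*X))\n")
  cat(sprintf("  theta1 = %.4f (se %.3g), theta2 = %.4f (se %.3g), theta3 = %.5f (se %.3g)\n",
              p[1], object@se[1], p[2], object@se[2], p[3], object@se[3]))
  cat(sprintf("  predicted equilibrium: %.2f degC; shape: %s\n",
              predictedEquilibrium(object), object@shapeClass))
  cat(sprintf("  converged: %s in %d iterations; RSS = %.4g; n = %d\n",
              object@converged, object@nIter, object@rss,
              length(object@data$x)))
  if (object@conditioningWarning)
    cat("  warning: ill-conditioned fit (near-linear response); SEs unreliable\n")
})

setMethod("show", "OnsetResult", function(object) {
  if (is.na(object@onsetTime)) {
    cat("OnsetResult: no wilting onset detected\n")
  } else {
    cat(sprintf("OnsetResult: onset at t = %g min (method: %s, peak drop %.1f %%/h)\n",
                object@onsetTime,
                object@diagnostics$method %||% "turgor_rate",
                object@diagnostics$peakDropRate %||% NA_real_))
  }
})

setMethod("show", "ScenarioConfig", function(object) {
  cat(sprintf("ScenarioConfig: %g days, %g:%g h photoperiod, air %g/%g degC day/night\n",
              object@nDays, object@photoperiod[1], object@photoperiod[2],
              object@dayAirTemp, object@nightAirTemp))
  cat(sprintf("  %g-min cadence, %g x %g px frames, noise sd %g degC, seed %g\n",
              object@cadence, object@frameShape[1], object@frameShape[2],
              object@noiseSd, object@seed))
  cat(sprintf("  wilting: Day %g after %g h light; pre-stress leaf-air offset %g degC\n",
              object@wiltDay, object@wiltHoursAfterLight,
              object@leafAirOffsetPrestress))
})

setMethod("show", "SceneGroundTruth", function(object) {
  cat(sprintf("SceneGroundTruth: %d truth rows, plants: %s\n",
              nrow(object@truth),
              paste(unique(object@truth$plant), collapse = ", ")))
  on <- object@wiltOnset
  cat("  wilt onset (min):",
      paste(sprintf("%s=%s", names(on), ifelse(is.na(on), "none", on)),
            collapse = ", "), "\n")
})
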