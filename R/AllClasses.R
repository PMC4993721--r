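#' @import methods
NULL

#' ThermalFrame: one radiometric thermal image
#'
#' A single radiometric frame: a 2-D grid of calibrated surface temperatures
#' (degrees Celsius) together with its acquisition timestamp (minutes since
#' the start of the experiment) and the emissivity setting used by the
#' camera. Pixel values are temperatures, not raw counts.
#'
#' @slot temperatures numeric matrix of surface temperatures, degrees C,
#'   indexed (row, column).
#' @slot timestamp acquisition time, minutes since experiment start.
#' @slot emissivity dimensionless emissivity in (0, 1]; thermal cameras in
#'   plant work conventionally use 0.95 for leaf material.
#' @slot frameId unique identifier string.
#'
#' @seealso [ThermalFrame()], [readFrame()], [writeFrame()], [roiExtract()]
#' @exportClass ThermalFrame
setClass("ThermalFrame",
  representation(
    temperatures = "matrix",
    timestamp    = "numeric",
    emissivity   = "numeric",
    frameId      = "character"
  ),
  prototype(
    timestamp  = 0,
    emissivity = 0.95,
    frameId    = "frame"
  )
)

setValidity("ThermalFrame", function(object) {
  m <- object@temperatures
  if (!is.numeric(m) || length(m) == 0L)
    return("temperatures must be a non-empty numeric matrix")
  if (any(!is.finite(m)))
    return("temperatures must all be finite")
  if (length(object@timestamp) != 1L || !is.finite(object@timestamp))
    return("timestamp must be a single finite number (minutes)")
  if (length(object@emissivity) != 1L ||
      object@emissivity <= 0 || object@emissivity > 1)
    return("emissivity must be a single value in (0, 1]")
  if (length(object@frameId) != 1L || !nzchar(object@frameId))
    return("frameId must be a single non-empty string")
  TRUE
})

#' Construct a ThermalFrame
#'
#' @param temperatures numeric matrix of temperatures in degrees C.
#' @param timestamp acquisition time, minutes since experiment start.
#' @param emissivity emissivity in (0, 1]; default 0.95.
#' @param frameId identifier string.
#' @param tempRange allowed physical range of temperatures, degrees C;
#'   values outside it are rejected as implausible for a plant-growth
#'   chamber scene.
#' @return a [ThermalFrame-class] object.
#' @examples
#' f <- ThermalFrame(matrix(c(28, 30, 29, 31), 2, 2), timestamp = 0)
#' temperatures(f)
#' @export
ThermalFrame <- function(temperatures, timestamp = 0, emissivity = 0.95,
                         frameId = "frame", tempRange = c(0, 60)) {
  if (!is.matrix(temperatures))
    temperatures <- as.matrix(temperatures)
  storage.mode(temperatures) <- "double"
  if (length(temperatures) == 0L)
    stop("temperature grid is empty")
  if (any(!is.finite(temperatures)))
    stop("temperature grid contains non-finite values")
  if (any(temperatures < tempRange[1] | temperatures > tempRange[2]))
    stop(sprintf("temperatures outside physical range [%g, %g] degC",
                 tempRange[1], tempRange[2]))
  new("ThermalFrame", temperatures = temperatures,
      timestamp = as.numeric(timestamp), emissivity = emissivity,
      frameId = as.character(frameId))
}

#' RegionOfInterest: a named pixel region within a frame
#'
#' Rectangular, oval or 3x3 point-cursor pixel regions, assigned either to a
#' plant or to the air-temperature cursor. Bounds are 0-based, half-open
#' `(row_min, col_min, row_max, col_max)`: the region covers pixel rows
#' `row_min .. row_max - 1` and columns `col_min .. col_max - 1`.
#'
#' @slot name label string.
#' @slot shape one of `"rectangle"`, `"oval"`, `"point_cursor"`.
#' @slot bounds numeric length-4 vector, 0-based half-open pixel bounds.
#' @slot role one of `"plant"`, `"air_cursor"`. An air cursor of shape
#'   `point_cursor` must cover exactly 3x3 pixels.
#' @slot anchor optional stem-anchor pixel `(row, col)`, 1-based, for plant
#'   ROIs; empty when not supplied.
#'
#' @seealso [RegionOfInterest()], [roiExtract()], [segmentPlant()]
#' @exportClass RegionOfInterest
setClass("RegionOfInterest",
  representation(
    name   = "character",
    shape  = "character",
    bounds = "numeric",
    role   = "character",
    anchor = "numeric"
  ),
  prototype(shape = "rectangle", role = "plant", anchor = numeric(0))
)

setValidity("RegionOfInterest", function(object) {
  if (!object@shape %in% c("rectangle", "oval", "point_cursor"))
    return("shape must be rectangle, oval or point_cursor")
  if (!object@role %in% c("plant", "air_cursor"))
    return("role must be plant or air_cursor")
  b <- object@bounds
  if (length(b) != 4L || any(!is.finite(b)))
    return("bounds must be numeric(4): row_min, col_min, row_max, col_max")
  if (any(b < 0) || b[3] <= b[1] || b[4] <= b[2])
    return("bounds must be non-negative with row_max > row_min and col_max > col_min")
  if (object@shape == "point_cursor" && object@role == "air_cursor" &&
      !(b[3] - b[1] == 3 && b[4] - b[2] == 3))
    return("an air-cursor point_cursor must cover exactly 3x3 pixels")
  if (length(object@anchor) %in% c(0L, 2L) == FALSE)
    return("anchor must be empty or a (row, col) pair")
  TRUE
})

#' Construct a RegionOfInterest
#'
#' @param name label string.
#' @param shape `"rectangle"`, `"oval"` or `"point_cursor"`.
#' @param bounds 0-based half-open `(row_min, col_min, row_max, col_max)`.
#' @param role `"plant"` or `"air_cursor"`.
#' @param anchor optional stem anchor `(row, col)`, 1-based pixel, for
#'   leaf-angle measurement.
#' @return a [RegionOfInterest-class] object.
#' @examples
#' RegionOfInterest("ctrl", "rectangle", c(0, 0, 20, 20), "plant")
#' @export
RegionOfInterest <- function(name, shape = "rectangle", bounds,
                             role = "plant", anchor = numeric(0)) {
  new("RegionOfInterest", name = as.character(name), shape = shape,
      bounds = as.numeric(bounds), role = role, anchor = as.numeric(anchor))
}

#' FrameSequence: an ordered time-lapse of thermal frames
#'
#' @slot frames list of [ThermalFrame-class] objects with strictly
#'   increasing timestamps and constant grid dimensions.
#' @slot cadence nominal sampling interval, minutes (default 10).
#' @slot rois list of [RegionOfInterest-class]; when non-empty must hold at
#'   least one plant ROI and exactly one air cursor.
#' @slot dayNightSchedule data.frame with columns `lightsOnMin`,
#'   `lightsOffMin` (minutes since experiment start), one row per day.
#'
#' @seealso [FrameSequence()], [generateSequence()], [readSequence()]
#' @exportClass FrameSequence
setClass("FrameSequence",
  representation(
    frames           = "list",
    cadence          = "numeric",
    rois             = "list",
    dayNightSchedule = "data.frame"
  ),
  prototype(cadence = 10,
            dayNightSchedule = data.frame(lightsOnMin = numeric(0),
                                          lightsOffMin = numeric(0)))
)

setValidity("FrameSequence", function(object) {
  fr <- object@frames
  if (length(fr) == 0L)
    return("sequence must contain at least one frame")
  if (!all(vapply(fr, is, logical(1), "ThermalFrame")))
    return("frames must all be ThermalFrame objects")
  ts <- vapply(fr, function(f) f@timestamp, numeric(1))
  if (any(diff(ts) <= 0))
    return("frame timestamps must be strictly increasing")
  dims <- vapply(fr, function(f) dim(f@temperatures), integer(2))
  if (length(fr) > 1L && any(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1]))
    return("grid dimensions must be constant across the sequence")
  if (length(fr) > 1L) {
    d <- diff(ts)
    if (any(abs(d - object@cadence) > 0.01 * object@cadence))
      return("successive timestamps inconsistent with cadence (>1% deviation)")
  }
  if (length(object@rois) > 0L) {
    if (!all(vapply(object@rois, is, logical(1), "RegionOfInterest")))
      return("rois must all be RegionOfInterest objects")
    roles <- vapply(object@rois, function(r) r@role, character(1))
    if (sum(roles == "air_cursor") != 1L)
      return("a scene must have exactly one air_cursor ROI")
    if (sum(roles == "plant") < 1L)
      return("a scene must have at least one plant ROI")
    dm <- dims[, 1]
    ok <- vapply(object@rois, function(r)
      r@bounds[3] <= dm[1] && r@bounds[4] <= dm[2], logical(1))
    if (!all(ok))
      return("all ROI bounds must lie within the frame dimensions")
  }
  TRUE
})

#' Construct a FrameSequence
#'
#' @param frames list of [ThermalFrame-class] objects.
#' @param cadence sampling interval, minutes.
#' @param rois list of [RegionOfInterest-class] objects.
#' @param dayNightSchedule data.frame with `lightsOnMin`, `lightsOffMin`.
#' @return a [FrameSequence-class] object.
#' @export
FrameSequence <- function(frames, cadence = 10, rois = list(),
                          dayNightSchedule =
                            data.frame(lightsOnMin = numeric(0),
                                       lightsOffMin = numeric(0))) {
  new("FrameSequence", frames = frames, cadence = as.numeric(cadence),
      rois = rois, dayNightSchedule = dayNightSchedule)
}

#' AsymptoticParams: parameters of the asymptotic stress-response model
#'
#' The model is `Y = theta1 - theta2 * exp(-theta3 * X) + eps`: `theta1` is
#' the equilibrium temperature (asymptote, degC), `theta2` the amplitude
#' (degC) and `theta3` the relaxation rate (per hour).
#'
#' @slot theta1 asymptote, degrees C.
#' @slot theta2 amplitude, degrees C.
#' @slot theta3 rate, per hour; positive.
#' @slot residualSd residual standard deviation, degrees C.
#' @seealso [fitAsymptotic()], [asymValue()]
#' @exportClass AsymptoticParams
setClass("AsymptoticParams",
  representation(theta1 = "numeric", theta2 = "numeric",
                 theta3 = "numeric", residualSd = "numeric"),
  prototype(residualSd = 0)
)

setValidity("AsymptoticParams", function(object) {
  for (s in c("theta1", "theta2", "theta3", "residualSd"))
    if (length(slot(object, s)) != 1L || !is.finite(slot(object, s)))
      return(sprintf("%s must be a single finite number", s))
  if (object@theta3 <= 0) return("theta3 (rate) must be positive")
  if (object@residualSd < 0) return("residualSd must be non-negative")
  TRUE
})

#' Construct AsymptoticParams
#'
#' @param theta1 asymptote, degrees C.
#' @param theta2 amplitude, degrees C.
#' @param theta3 rate, per hour.
#' @param residualSd residual standard deviation, degrees C.
#' @return an [AsymptoticParams-class] object.
#' @examples
#' AsymptoticParams(31.83, 4.0, 0.523)
#' @export
AsymptoticParams <- function(theta1, theta2, theta3, residualSd = 0) {
  new("AsymptoticParams", theta1 = as.numeric(theta1),
      theta2 = as.numeric(theta2), theta3 = as.numeric(theta3),
      residualSd = as.numeric(residualSd))
}

#' StressKineticsFit: a fitted asymptotic stress-response model
#'
#' @slot params fitted [AsymptoticParams-class].
#' @slot se named standard errors of the three parameters (from the
#'   Jacobian at the optimum); may be `NA` when the fit is ill-conditioned.
#' @slot converged logical convergence flag.
#' @slot nIter number of optimizer iterations used.
#' @slot rss residual sum of squares, squared degrees C.
#' @slot shapeClass `"asymptotic"` or `"near_linear"` at the fitting
#'   horizon (see [classifyResponseShape()]).
#' @slot residualDiagnostics list with normality (Shapiro-Wilk) and
#'   independence (Ljung-Box, lag 1) p-values and pass flags.
#' @slot data list with the fitted `x` (hours) and `y` (degC).
#' @slot conditioningWarning logical; `TRUE` when the Jacobian cross-product
#'   is numerically singular (typical of near-linear responses).
#' @seealso [fitAsymptotic()], [predictedEquilibrium()]
#' @exportClass StressKineticsFit
setClass("StressKineticsFit",
  representation(
    params              = "AsymptoticParams",
    se                  = "numeric",
    converged           = "logical",
    nIter               = "integer",
    rss                 = "numeric",
    shapeClass          = "character",
    residualDiagnostics = "list",
    data                = "list",
    conditioningWarning = "logical"
  )
)

#' OnsetResult: a detected wilting-onset time
#'
#' @slot onsetTime onset time in minutes since experiment start, or `NA`
#'   when no onset was found.
#' @slot diagnostics list: detection method, peak drop rate (%/h),
#'   thresholds used.
#' @seealso [detectWiltingOnset()]
#' @exportClass OnsetResult
setClass("OnsetResult",
  representation(onsetTime = "numeric", diagnostics = "list"))

#' ScenarioConfig: parameters of the synthetic stress-recovery scenario
#'
#' Describes the five-day drought stress and recovery trial that the
#' synthetic scene generator emulates: a growth chamber on a 16:8 h
#' photoperiod whose air temperature is 27 degC at night and 33 degC under
#' the lamps, two plants (one untreated control, one biostimulant-treated)
#' imaged every 10 minutes, transpiring leaves sitting 3 degC below air
#' temperature before stress, a wilting event on Day 3 after 5.5 h of light
#' in which the control leaf temperature relaxes asymptotically to (and
#' slightly above) air temperature while the treated leaf warms near-linearly,
#' leaf angles of about 55 degrees by day dropping to near zero at wilt, and
#' re-watering with recovery of the treated plant on Day 5.
#'
#' @slot nDays experiment length, days.
#' @slot dayAirTemp,nightAirTemp chamber air temperature, degC.
#' @slot photoperiod hours of light and dark; must sum to 24.
#' @slot cadence frame interval, minutes.
#' @slot leafAirOffsetPrestress pre-stress daytime leaf-air deficit, degC.
#' @slot nightOffset night-time leaf-air deficit, degC (stomata closed).
#' @slot wiltDay day index (1-based) of the control wilting event.
#' @slot wiltHoursAfterLight hours of light before wilting starts.
#' @slot controlKinetics,treatedKinetics [AsymptoticParams-class] driving
#'   post-onset leaf temperature for the two plants.
#' @slot treatedCapOffset minimum leaf-air deficit maintained by the
#'   treated plant, degC; its temperature never rises above air minus this.
#' @slot angleDay,angleNight daytime and night leaf angle, degrees.
#' @slot wiltAngleFloor residual angle of fully wilted leaves, degrees.
#' @slot wiltDurationMin duration of the control's angle collapse, minutes.
#' @slot treatedDeclineRate slow post-onset angle decline of the treated
#'   plant, degrees per hour.
#' @slot treatedStressAngle treated plant daytime angle on the adaptation
#'   day (Day 4), degrees.
#' @slot day1TransientC,day1TransientTauMin initial Day-1 relaxation of
#'   leaf temperature: starting excess (degC) and time constant (minutes).
#' @slot angleTransitionMin duration of the diurnal leaf rise/fold, minutes.
#' @slot rewaterHoursAfterLight re-watering time on the final day, hours
#'   after lights-on.
#' @slot recoveryHours duration of the treated plant's turgor recovery, h.
#' @slot recoveryOffset post-recovery leaf-air deficit, degC.
#' @slot noiseSd i.i.d. Gaussian pixel noise, degC (sensor resolution).
#' @slot frameShape frame dimensions `(rows, cols)` in pixels.
#' @slot leafLength,leafWidth rendered leaf dimensions, pixels.
#' @slot seed RNG seed used by [generateSequence()].
#' @seealso [scenarioConfig()], [generateSequence()]
#' @exportClass ScenarioConfig
setClass("ScenarioConfig",
  representation(
    nDays                  = "numeric",
    dayAirTemp             = "numeric",
    nightAirTemp           = "numeric",
    photoperiod            = "numeric",
    cadence                = "numeric",
    leafAirOffsetPrestress = "numeric",
    nightOffset            = "numeric",
    wiltDay                = "numeric",
    wiltHoursAfterLight    = "numeric",
    controlKinetics        = "AsymptoticParams",
    treatedKinetics        = "AsymptoticParams",
    treatedCapOffset       = "numeric",
    angleDay               = "numeric",
    angleNight             = "numeric",
    wiltAngleFloor         = "numeric",
    wiltDurationMin        = "numeric",
    treatedDeclineRate     = "numeric",
    treatedStressAngle     = "numeric",
    day1TransientC         = "numeric",
    day1TransientTauMin    = "numeric",
    angleTransitionMin     = "numeric",
    rewaterHoursAfterLight = "numeric",
    recoveryHours          = "numeric",
    recoveryOffset         = "numeric",
    noiseSd                = "numeric",
    frameShape             = "numeric",
    leafLength             = "numeric",
    leafWidth              = "numeric",
    seed                   = "numeric"
  )
)

setValidity("ScenarioConfig", function(object) {
  if (length(object@photoperiod) != 2L || sum(object@photoperiod) != 24)
    return("photoperiod must be two values (light, dark) summing to 24 h")
  if (object@noiseSd < 0) return("noiseSd must be non-negative")
  rng <- c(object@dayAirTemp, object@nightAirTemp)
  if (any(rng < 0 | rng > 60))
    return("air temperatures outside the physical range 0-60 degC")
  if (object@nDays < 1) return("nDays must be at least 1")
  if (object@wiltDay < 1 || object@wiltDay > object@nDays)
    return("wiltDay must lie within the experiment")
  if (object@wiltHoursAfterLight <= 0 ||
      object@wiltHoursAfterLight >= object@photoperiod[1])
    return("wiltHoursAfterLight must fall within the light period")
  if (length(object@frameShape) != 2L || any(object@frameShape < 16))
    return("frameShape must be (rows, cols), each at least 16 pixels")
  if (object@leafLength < 4 || object@leafWidth < 2)
    return("leaf dimensions too small to render")
  TRUE
})

#' SceneGroundTruth: the generator's true state per frame
#'
#' @slot truth data.frame with one row per frame and plant: `time` (min),
#'   `plant`, `treatment`, `leafTemp` (degC), `airTemp` (degC), `angle`
#'   (degrees), `daytime` (logical).
#' @slot wiltOnset named numeric of true onset times (minutes); `NA` for
#'   plants that never wilt.
#' @slot config the [ScenarioConfig-class] that produced the scene; leaf
#'   masks are re-derivable deterministically from it via [trueLeafMask()].
#' @seealso [generateSequence()], [trueLeafMask()]
#' @exportClass SceneGroundTruth
setClass("SceneGroundTruth",
  representation(truth = "data.frame", wiltOnset = "numeric",
                 config = "ScenarioConfig"))
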