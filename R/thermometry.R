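# Leaf and air temperature extraction from ROI statistics.
#
# Interpretation of ROI extremes changes across the wilting event: while
# the canopy transpires, the ROI minimum is leaf temperature (leaves are
# the coolest objects in the region) and the maximum reflects ambient;
# once a wilted canopy has equilibrated with (and risen above) air
# temperature, the maximum is the leaf/stem temperature and the lower tail
# reflects ambient. assignLeafTemperature() switches between the two modes
# with a margin-plus-hysteresis rule so the assignment cannot chatter near
# equilibrium.

#' Robust extreme temperature with apical-interference correction
#'
#' A wilting apical point bending into an ROI contaminates the raw
#' extremes. With at least `minPixels` pixel values the raw extreme is
#' replaced by a robust one: the 2nd percentile in `min_is_leaf` mode or
#' the 98th percentile in `max_is_leaf` mode; the reading is flagged
#' `corrected` when the two differ by more than `flagDelta` degC. With
#' fewer pixels the raw extreme is kept unflagged.
#'
#' @param values numeric vector of ROI pixel temperatures, degC.
#' @param mode `"min_is_leaf"` or `"max_is_leaf"`.
#' @param minPixels minimum number of pixels for the robust rule.
#' @param probs lower/upper percentile levels of the robust extremes.
#' @param flagDelta flagging threshold, degC.
#' @return list with `value` (the corrected extreme, degC), `raw` (the raw
#'   extreme) and `corrected` (logical).
#' @examples
#' apicalCorrect(c(rep(30, 100), 35), "max_is_leaf")
#' @export
apicalCorrect <- function(values, mode = c("min_is_leaf", "max_is_leaf"),
                          minPixels = 20, probs = c(0.02, 0.98),
                          flagDelta = 0.3) {
  mode <- match.arg(mode)
  raw <- if (mode == "min_is_leaf") min(values) else max(values)
  if (length(values) < minPixels)
    return(list(value = raw, raw = raw, corrected = FALSE))
  robust <- unname(stats::quantile(
    values, if (mode == "min_is_leaf") probs[1] else probs[2], names = FALSE))
  list(value = robust, raw = raw,
       corrected = abs(raw - robust) > flagDelta)
}

#' Per-frame ROI temperature readings
#'
#' For every frame and every plant ROI, computes the raw and robust ROI
#' extremes (see [apicalCorrect()]) and the air temperature as the mean of
#' the 3x3 air-cursor pixels.
#'
#' @param sequence a [FrameSequence-class] whose ROIs include at least one
#'   plant region and exactly one air cursor.
#' @param minPixels,probs,flagDelta passed to [apicalCorrect()].
#' @return data.frame with columns `frameId`, `time`, `plant`, `roiMin`,
#'   `roiMax`, `robustMin`, `robustMax`, `correctedMin`, `correctedMax`,
#'   `airTemp`.
#' @export
extractReadings <- function(sequence, minPixels = 20, probs = c(0.02, 0.98),
                            flagDelta = 0.3) {
  roles <- vapply(sequence@rois, function(r) r@role, character(1))
  cursor <- sequence@rois[roles == "air_cursor"]
  if (length(cursor) != 1L)
    stop("sequence must carry exactly one air_cursor ROI")
  cursor <- cursor[[1]]
  plantRois <- sequence@rois[roles == "plant"]
  out <- vector("list", length(sequence@frames) * length(plantRois))
  k <- 0L
  for (f in sequence@frames) {
    air <- mean(roiExtract(f, cursor))
    for (r in plantRois) {
      vals <- roiExtract(f, r)
      lo <- apicalCorrect(vals, "min_is_leaf", minPixels, probs, flagDelta)
      hi <- apicalCorrect(vals, "max_is_leaf", minPixels, probs, flagDelta)
      k <- k + 1L
      out[[k]] <- data.frame(
        frameId = f@frameId, time = f@timestamp, plant = r@name,
        roiMin = lo$raw, roiMax = hi$raw,
        robustMin = lo$value, robustMax = hi$value,
        correctedMin = lo$corrected, correctedMax = hi$corrected,
        airTemp = air, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Assign leaf temperature from ROI extremes
#'
#' Applies the pre/post-stress interpretation switch to a time-ordered set
#' of per-frame readings. Each plant starts in `min_is_leaf` mode (a
#' transpiring leaf is the coolest object in its ROI). The mode switches to
#' `max_is_leaf` once the ROI minimum no longer sits more than
#' `switchMargin` degC below air temperature *and* the ROI maximum exceeds
#' air temperature (the canopy has equilibrated and warmed past ambient).
#' A switch in either direction is blocked within `hysteresisMin` minutes
#' of the previous one, so the assignment cannot chatter when the canopy
#' hovers near equilibrium.
#'
#' @param readings data.frame as produced by [extractReadings()]; at
#'   minimum columns `time`, `plant`, `airTemp` and either robust
#'   (`robustMin`/`robustMax`) or raw (`roiMin`/`roiMax`) extremes.
#' @param switchMargin switch margin, degC.
#' @param hysteresisMin hysteresis dead time, minutes.
#' @return the readings with columns `leafTemp` (degC), `mode`
#'   (`"min_is_leaf"`/`"max_is_leaf"`) and `corrected` added.
#' @export
assignLeafTemperature <- function(readings, switchMargin = 0.5,
                                  hysteresisMin = 60) {
  if (!all(c("time", "plant", "airTemp") %in% names(readings)))
    stop("readings must have columns time, plant, airTemp")
  if (is.null(readings$robustMin)) readings$robustMin <- readings$roiMin
  if (is.null(readings$robustMax)) readings$robustMax <- readings$roiMax
  if (is.null(readings$correctedMin)) readings$correctedMin <- FALSE
  if (is.null(readings$correctedMax)) readings$correctedMax <- FALSE
  readings$leafTemp <- NA_real_
  readings$mode <- NA_character_
  readings$corrected <- NA
  for (p in unique(readings$plant)) {
    idx <- which(readings$plant == p)
    idx <- idx[order(readings$time[idx])]
    mode <- "min_is_leaf"
    lastSwitch <- -Inf
    for (i in idx) {
      air <- readings$airTemp[i]
      tm <- readings$time[i]
      canSwitch <- (tm - lastSwitch) >= hysteresisMin
      if (mode == "min_is_leaf") {
        if (canSwitch &&
            readings$robustMin[i] >= air - switchMargin &&
            readings$robustMax[i] > air) {
          mode <- "max_is_leaf"; lastSwitch <- tm
        }
      } else {
        if (canSwitch && readings$robustMin[i] < air - switchMargin) {
          mode <- "min_is_leaf"; lastSwitch <- tm
        }
      }
      if (mode == "min_is_leaf") {
        readings$leafTemp[i] <- readings$robustMin[i]
        readings$corrected[i] <- readings$correctedMin[i]
      } else {
        readings$leafTemp[i] <- readings$robustMax[i]
        readings$corrected[i] <- readings$correctedMax[i]
      }
      readings$mode[i] <- mode
    }
  }
  readings
}

#' Build per-plant time series of temperatures, angles and turgor
#'
#' Joins assigned leaf temperatures with leaf-angle measurements into the
#' tidy per-plant series used by the stress-kinetics stage.
#'
#' @param assigned data.frame from [assignLeafTemperature()].
#' @param angles optional data.frame from [measureAngles()] with columns
#'   `time`, `plant`, `angle`, `turgor`.
#' @param treatments optional named character vector mapping plant label to
#'   `"control"`/`"treated"`; defaults to the plant label itself when it
#'   already is one of the two.
#' @return data.frame with columns `plant`, `treatment`, `time`,
#'   `leafTemp`, `airTemp`, `delta` (leaf minus air, degC), `mode`,
#'   `corrected`, `leafAngle`, `turgor`.
#' @export
plantTimeSeries <- function(assigned, angles = NULL, treatments = NULL) {
  s <- assigned[order(assigned$plant, assigned$time),
                c("plant", "time", "leafTemp", "airTemp", "mode", "corrected")]
  s$treatment <- if (is.null(treatments)) {
    ifelse(s$plant %in% c("control", "treated"), s$plant, NA_character_)
  } else {
    unname(treatments[s$plant])
  }
  s$delta <- s$leafTemp - s$airTemp
  if (!is.null(angles)) {
    s <- merge(s, angles[, c("time", "plant", "angle", "turgor")],
               by = c("time", "plant"), all.x = TRUE, sort = FALSE)
    names(s)[names(s) == "angle"] <- "leafAngle"
  } else {
    s$leafAngle <- NA_real_
    s$turgor <- NA_real_
  }
  s <- s[order(s$plant, s$time),
         c("plant", "treatment", "time", "leafTemp", "airTemp", "delta",
           "mode", "corrected", "leafAngle", "turgor")]
  rownames(s) <- NULL
  s
}

#' Hourly aggregation of a plant time series
#'
#' Averages leaf temperature and turgor over each daytime hour of the
#' schedule (the arithmetic mean of the frames falling in that hour; six
#' frames at the 10-minute cadence). Hours with fewer frames than a full
#' complement (light transitions, gaps) are flagged `partial`; empty hours
#' yield `NA` and are flagged.
#'
#' @param series data.frame from [plantTimeSeries()] (columns `plant`,
#'   `time`, `leafTemp`; `turgor` optional).
#' @param schedule data.frame with `lightsOnMin`, `lightsOffMin` columns,
#'   one row per day.
#' @return data.frame with columns `plant`, `day`, `hour` (0-based within
#'   the light period), `timeMid` (minutes), `leafTemp`, `turgor`,
#'   `nFrames`, `partial`.
#' @export
hourlyAggregate <- function(series, schedule) {
  stopifnot(nrow(schedule) > 0)
  cad <- stats::median(diff(sort(unique(series$time))))
  if (60 %% cad != 0)
    stop("cadence (", cad, " min) must divide 60 min for hourly aggregation")
  full <- 60 / cad
  if (is.null(series$turgor)) series$turgor <- NA_real_
  rows <- list()
  for (p in unique(series$plant)) {
    sp <- series[series$plant == p, ]
    for (d in seq_len(nrow(schedule))) {
      on <- schedule$lightsOnMin[d]; off <- schedule$lightsOffMin[d]
      nh <- floor((off - on) / 60)
      for (h in seq_len(nh) - 1L) {
        lo <- on + 60 * h; hi <- min(lo + 60, off)
        inh <- sp$time >= lo & sp$time < hi
        n <- sum(inh)
        rows[[length(rows) + 1L]] <- data.frame(
          plant = p, day = d, hour = h,
          timeMid = if (n) mean(sp$time[inh]) else (lo + hi) / 2,
          leafTemp = if (n) mean(sp$leafTemp[inh]) else NA_real_,
          turgor = if (n && any(!is.na(sp$turgor[inh])))
            mean(sp$turgor[inh], na.rm = TRUE) else NA_real_,
          nFrames = n, partial = n < full, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
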