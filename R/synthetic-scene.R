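# Ground-truthed synthetic thermal scenes.
#
# The generator emulates a five-day drought stress-recovery trial in a
# growth chamber: two soybean-like plants (an untreated control and a
# biostimulant-treated plant) imaged every 10 minutes against a background
# at air temperature, a 16:8 photoperiod with air at 33 degC under the
# lamps and 27 degC at night, transpiring leaves ~3 degC below air before
# stress, a wilting event on Day 3 (control collapses; leaf temperature
# relaxes asymptotically past air temperature while the treated plant warms
# near-linearly and keeps a small leaf-air deficit), and re-watering with
# recovery of the treated plant on Day 5. All true leaf/air temperatures,
# leaf angles and the wilting-onset time are available as closed-form
# functions of the configuration, so every downstream stage can be tested
# against exact ground truth.

#' Construct a ScenarioConfig
#'
#' All arguments have defaults describing the reference stress-recovery
#' trial; see [ScenarioConfig-class] for the meaning and units of each.
#' The post-onset temperature kinetics default to asymptotic-model
#' parameter sets anchored at the scenario's own air temperature: the
#' control relaxes at 0.523 per hour to an equilibrium slightly above air
#' (a wilted, non-transpiring canopy under lamps), while the treated plant
#' warms at the near-linear rate 0.0098 per hour, capped just below air.
#'
#' @param nDays,dayAirTemp,nightAirTemp,photoperiod,cadence see
#'   [ScenarioConfig-class].
#' @param leafAirOffsetPrestress,nightOffset,wiltDay,wiltHoursAfterLight see
#'   [ScenarioConfig-class].
#' @param controlKinetics,treatedKinetics,treatedCapOffset see
#'   [ScenarioConfig-class].
#' @param angleDay,angleNight,wiltAngleFloor,wiltDurationMin see
#'   [ScenarioConfig-class].
#' @param treatedDeclineRate,treatedStressAngle see [ScenarioConfig-class].
#' @param day1TransientC,day1TransientTauMin,angleTransitionMin see
#'   [ScenarioConfig-class].
#' @param rewaterHoursAfterLight,recoveryHours,recoveryOffset see
#'   [ScenarioConfig-class].
#' @param noiseSd,frameShape,leafLength,leafWidth,seed see
#'   [ScenarioConfig-class].
#' @return a validated [ScenarioConfig-class].
#' @examples
#' cfg <- scenarioConfig(noiseSd = 0)
#' cfg
#' @export
scenarioConfig <- function(nDays = 5,
                           dayAirTemp = 33,
                           nightAirTemp = 27,
                           photoperiod = c(16, 8),
                           cadence = 10,
                           leafAirOffsetPrestress = 3.0,
                           nightOffset = 0.5,
                           wiltDay = 3,
                           wiltHoursAfterLight = 5.5,
                           controlKinetics =
                             AsymptoticParams(dayAirTemp + 0.8,
                                              dayAirTemp + 0.8 -
                                                (dayAirTemp - leafAirOffsetPrestress),
                                              0.523),
                           treatedKinetics =
                             AsymptoticParams(dayAirTemp - leafAirOffsetPrestress + 22,
                                              22, 0.0098),
                           treatedCapOffset = 1.2,
                           angleDay = 55,
                           angleNight = 20,
                           wiltAngleFloor = 3,
                           wiltDurationMin = 90,
                           treatedDeclineRate = 3,
                           treatedStressAngle = 40,
                           day1TransientC = 2,
                           day1TransientTauMin = 40,
                           angleTransitionMin = 60,
                           rewaterHoursAfterLight = 2,
                           recoveryHours = 2.5,
                           recoveryOffset = 2.5,
                           noiseSd = 0.1,
                           frameShape = c(120, 160),
                           leafLength = 35,
                           leafWidth = 9,
                           seed = 42) {
  new("ScenarioConfig",
      nDays = nDays, dayAirTemp = dayAirTemp, nightAirTemp = nightAirTemp,
      photoperiod = photoperiod, cadence = cadence,
      leafAirOffsetPrestress = leafAirOffsetPrestress,
      nightOffset = nightOffset, wiltDay = wiltDay,
      wiltHoursAfterLight = wiltHoursAfterLight,
      controlKinetics = controlKinetics, treatedKinetics = treatedKinetics,
      treatedCapOffset = treatedCapOffset, angleDay = angleDay,
      angleNight = angleNight, wiltAngleFloor = wiltAngleFloor,
      wiltDurationMin = wiltDurationMin,
      treatedDeclineRate = treatedDeclineRate,
      treatedStressAngle = treatedStressAngle,
      day1TransientC = day1TransientC,
      day1TransientTauMin = day1TransientTauMin,
      angleTransitionMin = angleTransitionMin,
      rewaterHoursAfterLight = rewaterHoursAfterLight,
      recoveryHours = recoveryHours, recoveryOffset = recoveryOffset,
      noiseSd = noiseSd, frameShape = as.numeric(frameShape),
      leafLength = leafLength, leafWidth = leafWidth, seed = seed)
}

dayLengthMin <- function(config) config@photoperiod[1] * 60

#' True wilting-onset time of the scenario, minutes
#'
#' @param config a [ScenarioConfig-class].
#' @return minutes since experiment start at which the control plant starts
#'   wilting.
#' @export
wiltOnsetMinutes <- function(config)
  (config@wiltDay - 1) * 1440 + config@wiltHoursAfterLight * 60

rewaterMinutes <- function(config)
  (config@nDays - 1) * 1440 + config@rewaterHoursAfterLight * 60

#' Scenario timeline helpers
#'
#' `isDaytime` reports whether each time falls in the light period;
#' `trueAirTemp` gives the chamber air temperature (degC) at each time.
#'
#' @param config a [ScenarioConfig-class].
#' @param time minutes since experiment start (vectorized).
#' @return logical (`isDaytime`) or numeric degC (`trueAirTemp`).
#' @export
isDaytime <- function(config, time) (time %% 1440) < dayLengthMin(config)

#' @rdname isDaytime
#' @export
trueAirTemp <- function(config, time)
  ifelse(isDaytime(config, time), config@dayAirTemp, config@nightAirTemp)

asymEval <- function(p, hours) p@theta1 - p@theta2 * exp(-p@theta3 * hours)

#' True leaf temperature of the scenario, degrees C
#'
#' Closed-form ground truth driving the generator (before pixel noise).
#' Pre-onset, leaves sit `leafAirOffsetPrestress` degC below air by day
#' (`nightOffset` at night), with an exponentially relaxing warm transient
#' at the start of Day 1. From the wilting onset, the control follows its
#' asymptotic kinetics for the remainder of the wilt day, then stays at the
#' kinetic asymptote by day and at air temperature by night (thermal
#' equilibrium of a non-transpiring canopy). The treated plant follows its
#' near-linear kinetics capped at `treatedCapOffset` degC below air, holds
#' that deficit through the adaptation day, and after re-watering widens it
#' to `recoveryOffset` degC over `recoveryHours` hours.
#'
#' @param config a [ScenarioConfig-class].
#' @param time minutes since experiment start (vectorized).
#' @param treatment `"control"` or `"treated"`.
#' @return numeric vector of leaf temperatures, degC.
#' @export
trueLeafTemp <- function(config, time, treatment = c("control", "treated")) {
  treatment <- match.arg(treatment)
  air <- trueAirTemp(config, time)
  day <- isDaytime(config, time)
  onset <- wiltOnsetMinutes(config)
  wiltDayEnd <- (config@wiltDay - 1) * 1440 + dayLengthMin(config)

  pre <- air - ifelse(day, config@leafAirOffsetPrestress, config@nightOffset) +
    ifelse(time < dayLengthMin(config),
           config@day1TransientC * exp(-time / config@day1TransientTauMin), 0)

  out <- pre
  h <- (time - onset) / 60
  if (treatment == "control") {
    k <- config@controlKinetics
    mid <- time >= onset & time < wiltDayEnd
    out[mid] <- asymEval(k, h[mid])
    late <- time >= wiltDayEnd
    out[late] <- ifelse(day[late], k@theta1, air[late])
  } else {
    k <- config@treatedKinetics
    cap <- air - config@treatedCapOffset
    mid <- time >= onset & time < wiltDayEnd
    out[mid] <- pmin(asymEval(k, h[mid]), cap[mid])
    rw <- rewaterMinutes(config)
    hold <- time >= wiltDayEnd & time < rw
    out[hold] <- cap[hold]
    rec <- time >= rw
    off <- config@treatedCapOffset +
      (config@recoveryOffset - config@treatedCapOffset) *
      pmin((time - rw) / 60 / config@recoveryHours, 1)
    out[rec] <- air[rec] - off[rec]
  }
  out
}

# Diurnal leaf-angle baseline: rise from the night angle over
# angleTransitionMin after lights-on, fold back after lights-off.
diurnalAngle <- function(config, time, dayAngle) {
  tod <- time %% 1440
  dl <- dayLengthMin(config)
  tr <- config@angleTransitionMin
  an <- config@angleNight
  ifelse(tod < dl,
         ifelse(tod < tr, an + (dayAngle - an) * tod / tr, dayAngle),
         ifelse(tod - dl < tr,
                dayAngle - (dayAngle - an) * (tod - dl) / tr, an))
}

#' True leaf angle of the scenario, degrees
#'
#' Ground-truth leaf angle against the downward stem axis: the diurnal
#' baseline rises to `angleDay` by day and folds to `angleNight` at night.
#' At wilting onset the control angle collapses linearly to
#' `wiltAngleFloor` over `wiltDurationMin` minutes and stays there; the
#' treated plant declines slowly at `treatedDeclineRate` degrees/h for the
#' rest of the wilt day, holds a reduced daytime angle
#' (`treatedStressAngle`) through the adaptation day, and recovers to
#' `angleDay` over `recoveryHours` hours after re-watering.
#'
#' @inheritParams trueLeafTemp
#' @return numeric vector of leaf angles, degrees.
#' @export
trueLeafAngle <- function(config, time, treatment = c("control", "treated")) {
  treatment <- match.arg(treatment)
  onset <- wiltOnsetMinutes(config)
  out <- diurnalAngle(config, time, config@angleDay)
  if (treatment == "control") {
    wilting <- time >= onset
    prog <- pmin((time[wilting] - onset) / config@wiltDurationMin, 1)
    out[wilting] <- config@angleDay -
      (config@angleDay - config@wiltAngleFloor) * prog
  } else {
    wiltDayEnd <- (config@wiltDay - 1) * 1440 + dayLengthMin(config)
    rw <- rewaterMinutes(config)
    mid <- time >= onset & time < wiltDayEnd
    out[mid] <- pmax(config@angleNight,
                     config@angleDay -
                       config@treatedDeclineRate * (time[mid] - onset) / 60)
    atDayEnd <- pmax(config@angleNight,
                     config@angleDay -
                       config@treatedDeclineRate * (wiltDayEnd - onset) / 60)
    # fold from the actual end-of-day angle in the night after the wilt day
    tr <- config@angleTransitionMin
    fold <- time >= wiltDayEnd & time < wiltDayEnd + tr
    out[fold] <- atDayEnd -
      (atDayEnd - config@angleNight) * (time[fold] - wiltDayEnd) / tr
    hold <- time >= wiltDayEnd + tr & time < rw
    out[hold] <- diurnalAngle(config, time[hold], config@treatedStressAngle)
    rec <- time >= rw
    recAngle <- config@treatedStressAngle +
      (config@angleDay - config@treatedStressAngle) *
      pmin((time[rec] - rw) / 60 / config@recoveryHours, 1)
    out[rec] <- diurnalAngle(config, time[rec], recAngle)
  }
  out
}

#' Scene layout: plant positions and regions of interest
#'
#' Places two plants symmetrically in the frame with rectangular plant ROIs
#' and a 3x3 air-temperature point cursor between them, and validates that
#' a rendered leaf can never leave its ROI at any permitted angle.
#'
#' @param config a [ScenarioConfig-class].
#' @return list with `plants` (data.frame: plant, treatment, anchorRow,
#'   anchorCol, side) and `rois` (list of [RegionOfInterest-class]).
#' @export
sceneLayout <- function(config) {
  H <- config@frameShape[1]; W <- config@frameShape[2]
  r0 <- round(0.125 * H); r1 <- round(0.875 * H)
  plants <- data.frame(
    plant = c("control", "treated"),
    treatment = c("control", "treated"),
    anchorRow = round(0.5 * H),
    anchorCol = c(round(0.3125 * W), round(0.6875 * W)),
    side = c(-1, 1),
    stringsAsFactors = FALSE)
  colBounds <- list(c(round(0.025 * W), round(0.475 * W)),
                    c(round(0.525 * W), round(0.975 * W)))
  L <- config@leafLength; hw <- config@leafWidth / 2
  roiList <- vector("list", 3L)
  for (i in 1:2) {
    cb <- colBounds[[i]]
    a <- plants[i, ]
    reach <- L + hw
    inner <- if (a$side < 0) a$anchorCol - reach else a$anchorCol + reach
    ok <- a$anchorRow + reach <= r1 && a$anchorRow - 0.5 * L - hw >= r0 &&
      inner >= cb[1] && inner <= cb[2] &&
      a$anchorCol - hw >= cb[1] && a$anchorCol + hw <= cb[2]
    if (!ok)
      stop("degenerate scenario: leaf of plant '", a$plant,
           "' cannot fit inside its ROI; reduce leafLength or enlarge frameShape")
    roiList[[i]] <- RegionOfInterest(a$plant, "rectangle",
                                     c(r0, cb[1], r1, cb[2]), "plant",
                                     anchor = c(a$anchorRow, a$anchorCol))
  }
  cr <- floor(H / 2) - 1; cc <- floor(W / 2) - 2
  roiList[[3]] <- RegionOfInterest("air", "point_cursor",
                                   c(cr, cc, cr + 3, cc + 3), "air_cursor")
  b1 <- roiList[[1]]@bounds; b2 <- roiList[[2]]@bounds; b3 <- roiList[[3]]@bounds
  overlaps <- function(a, b)
    a[1] < b[3] && b[1] < a[3] && a[2] < b[4] && b[2] < a[4]
  if (overlaps(b1, b2) || overlaps(b1, b3) || overlaps(b2, b3))
    stop("degenerate scenario: overlapping ROIs")
  list(plants = plants, rois = roiList)
}

#' Render a straight leaf as a pixel mask
#'
#' Renders an elongated leaf attached to a vertical stem at `stemAnchor`,
#' whose principal axis makes `angle` degrees with the downward stem axis
#' (0 = hanging along the stem, 90 = horizontal). The mask is the set of
#' pixels whose centres fall in an oriented `length` x `width` rectangle
#' extending from the anchor; its principal axis is recoverable by
#' [estimateLeafAngle()] to within 1 degree.
#'
#' @param angle leaf angle in degrees, in `[0, 120]`.
#' @param stemAnchor `(row, col)` pixel of the stem attachment, 1-based.
#' @param length,width leaf dimensions in pixels.
#' @param frameShape frame dimensions `(rows, cols)`.
#' @param side horizontal direction of the leaf: `+1` (towards higher
#'   columns) or `-1`.
#' @return two-column integer matrix of (row, col) pixel indices.
#' @examples
#' m <- renderLeafMask(45, c(30, 30), 18, 5, c(60, 60))
#' nrow(m)
#' @export
renderLeafMask <- function(angle, stemAnchor, length, width, frameShape,
                           side = 1) {
  if (!is.finite(angle) || angle < 0 || angle > 120)
    stop("angle must lie in [0, 120] degrees")
  a <- angle * pi / 180
  u <- c(cos(a), side * sin(a))          # along the leaf (row, col)
  nv <- c(-side * sin(a), cos(a))        # across the leaf
  anchor0 <- c(stemAnchor[1] - 0.5, stemAnchor[2] - 0.5)
  corners <- rbind(anchor0 + (width / 2) * nv,
                   anchor0 - (width / 2) * nv,
                   anchor0 + length * u + (width / 2) * nv,
                   anchor0 + length * u - (width / 2) * nv)
  if (any(corners[, 1] < 0) || any(corners[, 1] > frameShape[1]) ||
      any(corners[, 2] < 0) || any(corners[, 2] > frameShape[2]))
    stop("leaf mask clipped by the frame boundary")
  rows <- max(1, floor(min(corners[, 1]))):min(frameShape[1],
                                               ceiling(max(corners[, 1])) + 1)
  cols <- max(1, floor(min(corners[, 2]))):min(frameShape[2],
                                               ceiling(max(corners[, 2])) + 1)
  g <- cbind(row = rep(rows, times = length(cols)),
             col = rep(cols, each = length(rows)))
  relR <- g[, 1] - 0.5 - anchor0[1]
  relC <- g[, 2] - 0.5 - anchor0[2]
  tpro <- relR * u[1] + relC * u[2]
  spro <- relR * nv[1] + relC * nv[2]
  keep <- tpro >= 0 & tpro <= length & abs(spro) <= width / 2
  out <- g[keep, , drop = FALSE]
  storage.mode(out) <- "integer"
  out
}

#' Ground-truth leaf mask at a given time
#'
#' Re-derives the exact pixel mask the generator rendered for a plant at a
#' frame time, from the scenario configuration alone.
#'
#' @param x a [SceneGroundTruth-class] or [ScenarioConfig-class].
#' @param time frame time, minutes.
#' @param plant `"control"` or `"treated"`.
#' @return two-column integer matrix of (row, col) pixel indices.
#' @export
trueLeafMask <- function(x, time, plant = c("control", "treated")) {
  plant <- match.arg(plant)
  config <- if (is(x, "SceneGroundTruth")) x@config else x
  lay <- sceneLayout(config)
  p <- lay$plants[lay$plants$plant == plant, ]
  renderLeafMask(trueLeafAngle(config, time, plant),
                 c(p$anchorRow, p$anchorCol),
                 config@leafLength, config@leafWidth,
                 config@frameShape, side = p$side)
}

#' Generate a synthetic ground-truthed frame sequence
#'
#' Renders the full scenario: each frame holds background pixels at air
#' temperature, each plant's leaf mask filled with its true leaf
#' temperature, and (when `noiseSd > 0`) i.i.d. Gaussian pixel noise on
#' top. The same seed reproduces the sequence bit for bit.
#'
#' @param config a [ScenarioConfig-class].
#' @return list with `sequence` (a [FrameSequence-class], ROIs and
#'   day/night schedule attached) and `truth` (a
#'   [SceneGroundTruth-class]).
#' @examples
#' sc <- generateSequence(scenarioConfig(nDays = 1, wiltDay = 1,
#'                                       cadence = 120,
#'                                       frameShape = c(60, 80),
#'                                       leafLength = 16, leafWidth = 5,
#'                                       noiseSd = 0))
#' sc$sequence
#' @export
generateSequence <- function(config) {
  validObject(config)
  lay <- sceneLayout(config)
  H <- config@frameShape[1]; W <- config@frameShape[2]
  times <- seq(0, config@nDays * 1440 - config@cadence, by = config@cadence)
  set.seed(config@seed)

  truthList <- lapply(seq_len(nrow(lay$plants)), function(i) {
    p <- lay$plants[i, ]
    data.frame(time = times, plant = p$plant, treatment = p$treatment,
               leafTemp = trueLeafTemp(config, times, p$treatment),
               airTemp = trueAirTemp(config, times),
               angle = trueLeafAngle(config, times, p$treatment),
               daytime = isDaytime(config, times),
               stringsAsFactors = FALSE)
  })
  truth <- do.call(rbind, truthList)
  truth <- truth[order(truth$time, truth$plant), ]
  rownames(truth) <- NULL

  frameList <- vector("list", length(times))
  for (i in seq_along(times)) {
    tm <- times[i]
    air <- trueAirTemp(config, tm)
    m <- matrix(air, H, W)
    for (j in seq_len(nrow(lay$plants))) {
      p <- lay$plants[j, ]
      mask <- renderLeafMask(trueLeafAngle(config, tm, p$treatment),
                             c(p$anchorRow, p$anchorCol),
                             config@leafLength, config@leafWidth,
                             config@frameShape, side = p$side)
      m[mask] <- trueLeafTemp(config, tm, p$treatment)
    }
    if (config@noiseSd > 0)
      m <- m + matrix(stats::rnorm(H * W, 0, config@noiseSd), H, W)
    frameList[[i]] <- ThermalFrame(m, timestamp = tm,
                                   frameId = sprintf("f%05d", i))
  }

  schedule <- data.frame(
    lightsOnMin = (seq_len(config@nDays) - 1) * 1440,
    lightsOffMin = (seq_len(config@nDays) - 1) * 1440 + dayLengthMin(config))
  sequence <- FrameSequence(frameList, cadence = config@cadence,
                            rois = lay$rois, dayNightSchedule = schedule)
  onset <- c(control = wiltOnsetMinutes(config), treated = NA_real_)
  truthObj <- new("SceneGroundTruth", truth = truth, wiltOnset = onset,
                  config = config)
  list(sequence = sequence, truth = truthObj)
}

#' @rdname SceneGroundTruth-class
#' @param x a SceneGroundTruth
#' @export
groundTruth <- function(x) x@truth

#' @rdname SceneGroundTruth-class
#' @export
wiltOnset <- function(x) x@wiltOnset
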