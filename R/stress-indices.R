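# Thermal stress indices: the crop water stress index (CWSI) and the index
# of relative stomatal conductance (Ig), with optional calibration of Ig
# to absolute stomatal conductance.

#' Crop water stress index (CWSI)
#'
#' `CWSI = (T_canopy - T_nws) / (T_max - T_nws)`: 0 at the non-water-
#' stressed (well-watered) reference temperature and 1 at the dry-canopy
#' reference. Values outside `[0, 1]` are returned unclamped — they signal
#' that the references do not bracket the observation — and marked in the
#' `"outOfRange"` attribute.
#'
#' @param tCanopy canopy (leaf) temperature, degC; vectorized.
#' @param tNws non-water-stressed reference temperature, degC.
#' @param tMax dry-canopy reference temperature, degC; must exceed `tNws`.
#' @return numeric vector of index values with a logical `"outOfRange"`
#'   attribute.
#' @examples
#' cwsi(c(29, 30.5, 32), tNws = 29, tMax = 32)
#' @export
cwsi <- function(tCanopy, tNws, tMax) {
  if (any(!is.finite(c(tNws, tMax))) || any(tMax <= tNws))
    stop("degenerate references: tMax must exceed tNws")
  v <- (tCanopy - tNws) / (tMax - tNws)
  attr(v, "outOfRange") <- v < 0 | v > 1
  v
}

#' Index of relative stomatal conductance (Ig)
#'
#' `Ig = (T_dry - T_leaf) / (T_leaf - T_wet)`: 0 for a leaf at the dry
#' reference, increasing without bound as the leaf approaches the wet
#' reference. Under constant boundary-layer conditions Ig is proportional
#' to stomatal conductance (see [stomatalConductance()]).
#'
#' @param tLeaf leaf temperature, degC; must exceed `tWet` (the index is
#'   undefined at or below the wet reference).
#' @param tDry dry-leaf reference temperature, degC.
#' @param tWet wet-leaf reference temperature, degC; must be below `tDry`.
#' @return numeric vector of index values.
#' @examples
#' igIndex(30.25, tDry = 32, tWet = 28.5)
#' @export
igIndex <- function(tLeaf, tDry, tWet) {
  if (any(!is.finite(c(tDry, tWet))) || any(tWet >= tDry))
    stop("degenerate references: tDry must exceed tWet")
  if (any(tLeaf <= tWet))
    stop("Ig undefined: tLeaf must exceed the wet reference tWet")
  (tDry - tLeaf) / (tLeaf - tWet)
}

#' Stomatal conductance from Ig
#'
#' `g_s = G * Ig`, where `G` (m/s per Ig unit) is the slope of a
#' `g_s`-versus-`Ig` calibration regression obtained independently, e.g.
#' by porometry under the same environment.
#'
#' @param ig index of relative stomatal conductance (dimensionless).
#' @param G calibration constant, (m/s) per Ig unit; must be positive.
#' @return stomatal conductance, m/s.
#' @examples
#' stomatalConductance(1.2, G = 0.01)
#' @export
stomatalConductance <- function(ig, G) {
  if (!is.finite(G) || G <= 0)
    stop("calibration constant G must be positive")
  G * ig
}

#' Reference temperatures from a measured series
#'
#' A pragmatic convention for scenes without physical wet/dry reference
#' surfaces: the dry references (`tMax`, `tDry`) are taken as the mean
#' daytime air temperature, and the wet/non-water-stressed references
#' (`tNws`, `tWet`) as the mean daytime leaf temperature on the first day,
#' when soil water is non-limiting. These are a convention, not measured
#' references; supply measured values whenever available.
#'
#' @param series data.frame from [plantTimeSeries()].
#' @param schedule data.frame with `lightsOnMin`, `lightsOffMin`.
#' @return list with `tNws`, `tMax`, `tDry`, `tWet` (degC).
#' @export
referencesFromSeries <- function(series, schedule) {
  day1 <- series$time >= schedule$lightsOnMin[1] &
    series$time < schedule$lightsOffMin[1]
  daytime <- rep(FALSE, nrow(series))
  for (d in seq_len(nrow(schedule)))
    daytime <- daytime | (series$time >= schedule$lightsOnMin[d] &
                            series$time < schedule$lightsOffMin[d])
  dry <- mean(series$airTemp[daytime])
  wet <- mean(series$leafTemp[day1])
  if (wet >= dry)
    stop("degenerate references derived from series (wet >= dry)")
  list(tNws = wet, tMax = dry, tDry = dry, tWet = wet)
}

#' Per-frame stress-index table
#'
#' Computes CWSI, Ig and (when a calibration constant is supplied)
#' stomatal conductance for every row of a plant time series. Ig is `NA`
#' where the leaf temperature does not exceed the wet reference.
#'
#' @param series data.frame from [plantTimeSeries()].
#' @param refs list with `tNws`, `tMax`, `tDry`, `tWet` (degC), e.g. from
#'   [referencesFromSeries()].
#' @param G optional calibration constant (m/s per Ig unit); when `NULL`
#'   no conductance column is produced.
#' @return data.frame with columns `time`, `plant`, `treatment`, `cwsi`,
#'   `cwsiFlag` (outside `[0, 1]`), `ig`, `delta` (degC) and optionally
#'   `gs` (m/s).
#' @export
indexTable <- function(series, refs, G = NULL) {
  v <- cwsi(series$leafTemp, refs$tNws, refs$tMax)
  out <- data.frame(
    time = series$time, plant = series$plant,
    treatment = series$treatment,
    cwsi = as.numeric(v), cwsiFlag = attr(v, "outOfRange"),
    ig = NA_real_, delta = series$leafTemp - series$airTemp,
    stringsAsFactors = FALSE)
  okIg <- series$leafTemp > refs$tWet
  out$ig[okIg] <- igIndex(series$leafTemp[okIg], refs$tDry, refs$tWet)
  if (!is.null(G)) out$gs <- stomatalConductance(out$ig, G)
  out
}
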