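# Thermal segmentation of plant pixels and principal-axis leaf-angle
# measurement ("digital protractor" against the vertical stem axis).

# Largest 8-connected component of TRUE cells in a logical matrix.
# Returns a logical matrix of the same shape. Masks are small (an ROI), so
# a frontier-expansion flood fill in plain R is adequate.
largestComponent <- function(mask) {
  n <- sum(mask)
  if (n == 0L) return(mask)
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nextLab <- 0L
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  sizes <- integer(0)
  todo <- which(mask)
  for (s in todo) {
    if (lab[s] != 0L) next
    nextLab <- nextLab + 1L
    frontier <- s
    lab[s] <- nextLab
    sz <- 1L
    while (length(frontier)) {
      fr <- ((frontier - 1L) %% H) + 1L
      fc <- ((frontier - 1L) %/% H) + 1L
      nbr <- integer(0)
      for (k in seq_len(nrow(offs))) {
        r <- fr + offs$dr[k]; c <- fc + offs$dc[k]
        ok <- r >= 1L & r <= H & c >= 1L & c <= W
        if (any(ok)) nbr <- c(nbr, (c[ok] - 1L) * H + r[ok])
      }
      nbr <- unique(nbr[mask[nbr] & lab[nbr] == 0L])
      lab[nbr] <- nextLab
      sz <- sz + length(nbr)
      frontier <- nbr
    }
    sizes[nextLab] <- sz
  }
  lab == which.max(sizes)
}

#' Segment plant pixels within an ROI by thermal contrast
#'
#' Plant pixels are those whose temperature differs from air temperature by
#' more than `threshold` degC (in either direction: transpiring leaves are
#' cooler than air, wilted sunlit leaves can be warmer), restricted to the
#' ROI; of these, only the largest 8-connected component is retained.
#' Because the rule is contrast-based it is invariant to adding a common
#' offset to leaf and air temperatures.
#'
#' @param frame a [ThermalFrame-class].
#' @param roi a plant [RegionOfInterest-class].
#' @param airTemp air temperature at the frame time, degC.
#' @param threshold contrast threshold, degC; the default 0.8 sits well
#'   below the pre-stress leaf-air deficit (3 degC) and well above sensor
#'   noise (0.1 degC).
#' @return two-column integer matrix of (row, col) plant-pixel indices in
#'   frame coordinates; zero rows when nothing exceeds the contrast.
#' @export
segmentPlant <- function(frame, roi, airTemp, threshold = 0.8) {
  m <- frame@temperatures
  idx <- roiPixelIndices(roi, dim(m))
  hot <- abs(m[idx] - airTemp) > threshold
  if (!any(hot))
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("row", "col"))))
  rows <- range(idx[, 1]); cols <- range(idx[, 2])
  sub <- matrix(FALSE, diff(rows) + 1L, diff(cols) + 1L)
  sub[cbind(idx[hot, 1] - rows[1] + 1L, idx[hot, 2] - cols[1] + 1L)] <- TRUE
  keep <- largestComponent(sub)
  w <- which(keep, arr.ind = TRUE)
  out <- cbind(row = w[, 1] + rows[1] - 1L, col = w[, 2] + cols[1] - 1L)
  storage.mode(out) <- "integer"
  out
}

#' Measure the leaf angle of a segmented plant mask
#'
#' The digital-protractor operation: the angle between the mask's principal
#' axis (leading eigenvector of the pixel-coordinate covariance, oriented
#' away from the stem anchor) and the downward vertical stem axis. 0
#' degrees is a leaf hanging along the stem, 90 degrees a horizontal leaf;
#' angles are clamped to `[0, 120]`.
#'
#' @param mask two-column (row, col) pixel matrix from [segmentPlant()] or
#'   [renderLeafMask()].
#' @param stemAnchor stem-attachment pixel `(row, col)`, 1-based.
#' @param minPixels smallest mask for which an angle is reported.
#' @param minEigRatio smallest leading/trailing eigenvalue ratio for an
#'   unambiguous axis.
#' @return list with `angle` (degrees, `NA` when not measurable), `turgor`
#'   (%, via [angleToTurgor()]), `nPixels`, and `quality` (`"ok"`,
#'   `"small_mask"` or `"ambiguous_axis"`).
#' @examples
#' m <- renderLeafMask(60, c(30, 30), 18, 5, c(60, 60))
#' estimateLeafAngle(m, c(30, 30))
#' @export
estimateLeafAngle <- function(mask, stemAnchor, minPixels = 30,
                              minEigRatio = 1.2) {
  n <- nrow(mask)
  if (n < minPixels)
    return(list(angle = NA_real_, turgor = NA_real_, nPixels = n,
                quality = "small_mask"))
  ctr <- colMeans(mask)
  cc <- stats::cov(mask)
  eg <- eigen(cc, symmetric = TRUE)
  ratio <- eg$values[1] / max(eg$values[2], .Machine$double.eps)
  if (ratio < minEigRatio)
    return(list(angle = NA_real_, turgor = NA_real_, nPixels = n,
                quality = "ambiguous_axis"))
  v <- eg$vectors[, 1]
  away <- c(ctr[1] - stemAnchor[1], ctr[2] - stemAnchor[2])
  if (sum(v * away) < 0) v <- -v
  # angle to the downward vertical (+row direction)
  ang <- acos(clamp(v[1] / sqrt(sum(v^2)), -1, 1)) * 180 / pi
  ang <- clamp(ang, 0, 120)
  list(angle = ang, turgor = angleToTurgor(ang), nPixels = n,
       quality = "ok")
}

#' Map leaf angle to a turgor index
#'
#' Linear mapping between leaf angle and turgor pressure index: 90 degrees
#' (horizontal leaf, full turgor) maps to 100 %, 0 degrees (hanging leaf,
#' wilted) to 0 %. Angles beyond 90 degrees saturate at 100 %.
#'
#' @param angle leaf angle in degrees; must be non-negative.
#' @return turgor index in percent, in `[0, 100]`.
#' @examples
#' angleToTurgor(c(0, 45, 90, 110))
#' @export
angleToTurgor <- function(angle) {
  if (any(!is.na(angle) & angle < 0))
    stop("leaf angle must be non-negative")
  clamp(angle / 90 * 100, 0, 100)
}

#' Measure leaf angles across a frame sequence
#'
#' Runs [segmentPlant()] and [estimateLeafAngle()] for every plant ROI in
#' every frame, using the 3x3 air cursor for the contrast reference. Plant
#' ROIs must carry stem anchors (see [RegionOfInterest()]).
#'
#' @param sequence a [FrameSequence-class].
#' @param threshold segmentation contrast threshold, degC.
#' @param minPixels,minEigRatio passed to [estimateLeafAngle()].
#' @return data.frame with columns `time`, `plant`, `angle` (degrees),
#'   `turgor` (%), `nPixels`, `quality`.
#' @export
measureAngles <- function(sequence, threshold = 0.8, minPixels = 30,
                          minEigRatio = 1.2) {
  roles <- vapply(sequence@rois, function(r) r@role, character(1))
  cursor <- sequence@rois[roles == "air_cursor"]
  if (length(cursor) != 1L)
    stop("sequence must carry exactly one air_cursor ROI")
  cursor <- cursor[[1]]
  plantRois <- sequence@rois[roles == "plant"]
  noAnchor <- vapply(plantRois, function(r) length(r@anchor) != 2L, logical(1))
  if (any(noAnchor))
    stop("plant ROI(s) without stem anchor: ",
         paste(vapply(plantRois[noAnchor], function(r) r@name, character(1)),
               collapse = ", "))
  rows <- vector("list", length(sequence@frames) * length(plantRois))
  k <- 0L
  for (f in sequence@frames) {
    air <- mean(roiExtract(f, cursor))
    for (r in plantRois) {
      mask <- segmentPlant(f, r, air, threshold)
      est <- estimateLeafAngle(mask, r@anchor, minPixels, minEigRatio)
      k <- k + 1L
      rows[[k]] <- data.frame(
        time = f@timestamp, plant = r@name, angle = est$angle,
        turgor = est$turgor, nPixels = est$nPixels, quality = est$quality,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
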