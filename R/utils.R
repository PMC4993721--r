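`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# 1-based row/col index ranges of a 0-based half-open ROI bounding box
roiRowCols <- function(roi) {
  b <- roi@bounds
  list(rows = (b[1] + 1):b[3], cols = (b[2] + 1):b[4])
}

stopIfOutside <- function(roi, dims) {
  b <- roi@bounds
  if (b[1] < 0 || b[2] < 0 || b[3] > dims[1] || b[4] > dims[2])
    stop(sprintf("ROI '%s' [%g,%g,%g,%g) lies outside the %d x %d frame",
                 roi@name, b[1], b[2], b[3], b[4], dims[1], dims[2]))
  invisible(TRUE)
}

#' Pixel indices covered by a region of interest
#'
#' @param roi a [RegionOfInterest-class].
#' @param dims frame dimensions `(rows, cols)`.
#' @return two-column integer matrix of (row, col) pixel indices, 1-based,
#'   in row-major order. For ovals, pixels whose centres fall inside the
#'   ellipse inscribed in the bounding box.
#' @export
roiPixelIndices <- function(roi, dims) {
  stopIfOutside(roi, dims)
  rc <- roiRowCols(roi)
  g <- cbind(row = rep(rc$rows, each = length(rc$cols)),
             col = rep(rc$cols, times = length(rc$rows)))
  if (roi@shape == "oval") {
    b <- roi@bounds
    cr <- (b[1] + b[3]) / 2
    cc <- (b[2] + b[4]) / 2
    ar <- (b[3] - b[1]) / 2
    ac <- (b[4] - b[2]) / 2
    # pixel (i, j) 1-based has 0-based centre (i - 0.5, j - 0.5)
    keep <- ((g[, 1] - 0.5 - cr) / ar)^2 + ((g[, 2] - 0.5 - cc) / ac)^2 <= 1
    g <- g[keep, , drop = FALSE]
  }
  storage.mode(g) <- "integer"
  g
}
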