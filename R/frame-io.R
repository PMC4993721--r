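# Readers and writers for radiometric frames and sequences.
#
# On-disk conventions:
#   * temperature CSV: one row of comma-separated degC values per pixel row,
#     '.' decimal separator, no header.
#   * float TIFF: single-channel 32-bit IEEE floating-point TIFF, pixel
#     value = degC. Reading uses tiff::readTIFF (libtiff handles float
#     samples natively); writing uses a minimal single-strip float writer
#     because no installed writer can emit float samples.
#   * every written frame gets a JSON sidecar <path>.json with frame_id,
#     timestamp_min and emissivity.
#   * sequence manifest: CSV with columns frame_id, path, timestamp_min;
#     paths are relative to the manifest.

frameFormat <- function(path, format = c("auto", "csv", "tiff")) {
  format <- match.arg(format)
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) "tiff" else "csv"
}

readTemperatureCsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty temperature CSV: ", path)
  cells <- strsplit(lines, ",", fixed = TRUE)
  ncols <- lengths(cells)
  if (any(ncols != ncols[1])) {
    bad <- which(ncols != ncols[1])[1]
    stop(sprintf("ragged temperature grid in %s: row %d has %d values, expected %d",
                 path, bad, ncols[bad], ncols[1]))
  }
  vals <- suppressWarnings(as.numeric(unlist(cells, use.names = FALSE)))
  if (any(!is.finite(vals)))
    stop("temperature grid in ", path, " contains non-finite or non-numeric values")
  matrix(vals, nrow = length(lines), ncol = ncols[1], byrow = TRUE)
}

writeTemperatureCsv <- function(m, path) {
  lines <- apply(m, 1L, function(r)
    paste(formatC(r, format = "f", digits = 6), collapse = ","))
  writeLines(lines, path)
}

# Minimal single-strip, little-endian, 32-bit float TIFF (SampleFormat 3).
writeFloatTiff <- function(m, path) {
  h <- nrow(m); w <- ncol(m)
  dataBytes <- 4L * h * w
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, nchars = 2, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(8L + dataBytes, con, size = 4, endian = "little")     # IFD offset
  writeBin(as.numeric(t(m)), con, size = 4, endian = "little")   # pixels
  entry <- function(tag, type, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(1L, con, size = 4, endian = "little")
    if (type == 3L) {                       # SHORT, left-justified + pad
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {                                # LONG
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  writeBin(10L, con, size = 2, endian = "little")  # entry count
  entry(256L, 4L, w)          # ImageWidth
  entry(257L, 4L, h)          # ImageLength
  entry(258L, 3L, 32L)        # BitsPerSample
  entry(259L, 3L, 1L)         # Compression: none
  entry(262L, 3L, 1L)         # Photometric: BlackIsZero
  entry(273L, 4L, 8L)         # StripOffsets
  entry(277L, 3L, 1L)         # SamplesPerPixel
  entry(278L, 4L, h)          # RowsPerStrip
  entry(279L, 4L, dataBytes)  # StripByteCounts
  entry(339L, 3L, 3L)         # SampleFormat: IEEE float
  writeBin(0L, con, size = 4, endian = "little")   # no next IFD
  invisible(path)
}

sidecarPath <- function(path) paste0(path, ".json")

#' Read a radiometric frame from disk
#'
#' Reads a temperature grid from a plain CSV of degC values or a
#' single-channel 32-bit float TIFF. If a JSON sidecar `<path>.json` exists
#' it supplies the frame id, timestamp and emissivity; otherwise defaults
#' apply (timestamp 0, emissivity 0.95, id from the file name).
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"csv"` or `"tiff"`.
#' @param tempRange allowed physical temperature range, degC.
#' @return a [ThermalFrame-class].
#' @seealso [writeFrame()]
#' @export
readFrame <- function(path, format = c("auto", "csv", "tiff"),
                      tempRange = c(0, 60)) {
  if (!file.exists(path)) stop("no such frame file: ", path)
  fmt <- frameFormat(path, format)
  m <- if (fmt == "csv") {
    readTemperatureCsv(path)
  } else {
    x <- tiff::readTIFF(path)
    if (length(dim(x)) > 2L)
      stop("expected a single-channel TIFF: ", path)
    if (any(!is.finite(x)))
      stop("temperature grid in ", path, " contains non-finite values")
    x
  }
  meta <- list(frame_id = tools::file_path_sans_ext(basename(path)),
               timestamp_min = 0, emissivity = 0.95)
  sc <- sidecarPath(path)
  if (file.exists(sc))
    meta <- utils::modifyList(meta, jsonlite::read_json(sc))
  ThermalFrame(m, timestamp = meta$timestamp_min,
               emissivity = meta$emissivity, frameId = meta$frame_id,
               tempRange = tempRange)
}

#' Write a radiometric frame to disk
#'
#' Writes the temperature grid (CSV of degC values, or 32-bit float TIFF
#' with pixel value = degC) plus a JSON metadata sidecar `<path>.json`
#' recording the frame id, timestamp and emissivity. Grids round-trip
#' through [readFrame()] within 1e-4 degC for both formats.
#'
#' @param frame a [ThermalFrame-class].
#' @param path destination file path.
#' @param format `"auto"` (by extension), `"csv"` or `"tiff"`.
#' @return the path, invisibly.
#' @export
writeFrame <- function(frame, path, format = c("auto", "csv", "tiff")) {
  stopifnot(is(frame, "ThermalFrame"))
  validObject(frame)
  fmt <- frameFormat(path, format)
  m <- frame@temperatures
  if (fmt == "csv") writeTemperatureCsv(m, path) else writeFloatTiff(m, path)
  jsonlite::write_json(
    list(frame_id = frame@frameId, timestamp_min = frame@timestamp,
         emissivity = frame@emissivity),
    sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname roiExtract
#' @export
setMethod("roiExtract", signature("ThermalFrame", "RegionOfInterest"),
  function(frame, roi) {
    idx <- roiPixelIndices(roi, dim(frame@temperatures))
    frame@temperatures[idx]
  })

#' Read an ROI configuration file
#'
#' The configuration is a YAML or JSON list of regions, each with fields
#' `name`, `shape`, `role`, `bounds` (0-based half-open
#' row_min, col_min, row_max, col_max) and optionally `anchor`
#' (1-based stem-anchor row, col for plant ROIs).
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON (`.json`) file.
#' @return list of [RegionOfInterest-class] objects.
#' @seealso [writeRoiConfig()]
#' @export
readRoiConfig <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  lapply(raw, function(e) {
    RegionOfInterest(e$name, e$shape %||% "rectangle",
                     unlist(e$bounds), e$role %||% "plant",
                     anchor = unlist(e$anchor) %||% numeric(0))
  })
}

#' Write an ROI configuration file
#'
#' @param rois list of [RegionOfInterest-class] objects.
#' @param path destination `.yaml`/`.yml` or `.json` file.
#' @return the path, invisibly.
#' @export
writeRoiConfig <- function(rois, path) {
  raw <- lapply(rois, function(r) {
    e <- list(name = r@name, shape = r@shape, role = r@role,
              bounds = as.numeric(r@bounds))
    if (length(r@anchor) == 2L) e$anchor <- as.numeric(r@anchor)
    e
  })
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(raw, path)
  }
  invisible(path)
}

#' Read a frame sequence from a manifest
#'
#' @param manifest CSV with columns `frame_id`, `path`, `timestamp_min`;
#'   frame paths are resolved relative to the manifest's directory.
#' @param roiConfig optional ROI configuration path (see [readRoiConfig()]).
#' @param dayNightSchedule optional data.frame with `lightsOnMin`,
#'   `lightsOffMin` columns.
#' @param cadence sampling interval in minutes; inferred from timestamps
#'   when `NULL`.
#' @return a [FrameSequence-class].
#' @seealso [writeSequence()]
#' @export
readSequence <- function(manifest, roiConfig = NULL,
                         dayNightSchedule = NULL, cadence = NULL) {
  man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("frame_id", "path", "timestamp_min")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  man <- man[order(man$timestamp_min), , drop = FALSE]
  base <- dirname(manifest)
  frameList <- lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, man$path[i])
    if (!file.exists(p))
      stop(sprintf("frame '%s' is missing: file %s not found",
                   man$frame_id[i], man$path[i]))
    f <- readFrame(p)
    f@frameId <- as.character(man$frame_id[i])
    f@timestamp <- as.numeric(man$timestamp_min[i])
    f
  })
  if (is.null(cadence)) {
    d <- diff(man$timestamp_min)
    cadence <- if (length(d)) stats::median(d) else 10
  }
  roiList <- if (is.null(roiConfig)) list() else readRoiConfig(roiConfig)
  if (is.null(dayNightSchedule))
    dayNightSchedule <- data.frame(lightsOnMin = numeric(0),
                                   lightsOffMin = numeric(0))
  FrameSequence(frameList, cadence = cadence, rois = roiList,
                dayNightSchedule = dayNightSchedule)
}

#' Write a frame sequence, manifest and ROI configuration
#'
#' @param sequence a [FrameSequence-class].
#' @param dir output directory (created if needed).
#' @param format frame format, `"csv"` or `"tiff"`.
#' @return the manifest path, invisibly.
#' @export
writeSequence <- function(sequence, dir, format = c("csv", "tiff")) {
  format <- match.arg(format)
  ext <- if (format == "csv") "csv" else "tif"
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rel <- vapply(sequence@frames, function(f)
    sprintf("%s.%s", f@frameId, ext), character(1))
  for (i in seq_along(sequence@frames))
    writeFrame(sequence@frames[[i]], file.path(dir, rel[i]), format)
  man <- data.frame(
    frame_id = vapply(sequence@frames, frameId, character(1)),
    path = rel,
    timestamp_min = vapply(sequence@frames, timestamp, numeric(1)))
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(man, manifest, row.names = FALSE, quote = FALSE)
  if (length(sequence@rois))
    writeRoiConfig(sequence@rois, file.path(dir, "rois.yaml"))
  if (nrow(sequence@dayNightSchedule))
    utils::write.csv(sequence@dayNightSchedule,
                     file.path(dir, "schedule.csv"), row.names = FALSE)
  invisible(manifest)
}
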