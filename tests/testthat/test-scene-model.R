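# Frame containers, ROI extraction and file round trips.

test_that("CSV frames read back with correct values and metadata", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("28.0,29.0", "30.0,31.0"), p)
  f <- readFrame(p)
  expect_s4_class(f, "ThermalFrame")
  expect_equal(dim(temperatures(f)), c(2L, 2L))
  expect_equal(max(temperatures(f)), 31.0)
  expect_equal(min(temperatures(f)), 28.0)
  expect_equal(emissivity(f), 0.95)

  # row-major full-frame extraction
  roi <- RegionOfInterest("all", "rectangle", c(0, 0, 2, 2))
  expect_equal(roiExtract(f, roi), c(28, 29, 30, 31))
})

test_that("malformed grids are rejected with informative errors", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("28.0,29.0", "30.0"), p)
  expect_error(readFrame(p), "row 2")

  writeLines(c("28.0,NaN", "30.0,31.0"), p)
  expect_error(readFrame(p), "non-finite")

  expect_error(ThermalFrame(matrix(numeric(0), 0, 0)), "empty")
  expect_error(ThermalFrame(matrix(c(28, 99), 1, 2)), "physical range")
})

test_that("CSV and float TIFF round-trip within 1e-4 degC", {
  set.seed(7)
  m <- matrix(runif(20 * 30, 25, 35), 20, 30)
  f <- ThermalFrame(m, timestamp = 120, emissivity = 0.95, frameId = "rt")
  for (ext in c(".csv", ".tif")) {
    p <- withr::local_tempfile(fileext = ext)
    writeFrame(f, p)
    g <- readFrame(p)
    expect_lt(max(abs(temperatures(g) - m)), 1e-4)
    expect_equal(timestamp(g), 120)
    expect_equal(frameId(g), "rt")
    # sidecar records the emissivity setting
    meta <- jsonlite::read_json(paste0(p, ".json"))
    expect_equal(meta$emissivity, 0.95)
  }
})

test_that("our float TIFFs are readable by the system TIFF reader", {
  m <- matrix(seq(20, 40, length.out = 12), 3, 4)
  p <- withr::local_tempfile(fileext = ".tif")
  writeFrame(ThermalFrame(m), p)
  direct <- tiff::readTIFF(p)
  expect_lt(max(abs(direct - m)), 1e-4)
})

test_that("point cursors and ovals extract the expected pixels", {
  f <- uniformFrame(30, c(10, 10))
  cur <- RegionOfInterest("air", "point_cursor", c(2, 2, 5, 5),
                          role = "air_cursor")
  expect_equal(roiExtract(f, cur), rep(30, 9))

  one <- RegionOfInterest("px", "rectangle", c(3, 4, 4, 5))
  expect_equal(roiExtract(f, one), temperatures(f)[4, 5])

  rect <- RegionOfInterest("r", "rectangle", c(1, 1, 9, 7))
  oval <- RegionOfInterest("o", "oval", c(1, 1, 9, 7))
  expect_equal(length(roiExtract(f, rect)), 8 * 6)
  expect_lte(length(roiExtract(f, oval)), length(roiExtract(f, rect)))
  expect_gt(length(roiExtract(f, oval)), 0)

  out <- RegionOfInterest("bad", "rectangle", c(0, 0, 11, 11))
  expect_error(roiExtract(f, out), "outside")

  expect_error(
    validObject(RegionOfInterest("air", "point_cursor", c(0, 0, 2, 2),
                                 role = "air_cursor")),
    "3x3")
})

test_that("sequence validity enforces ordering, dimensions and cadence", {
  fr <- function(t, dims = c(4, 4))
    ThermalFrame(matrix(30, dims[1], dims[2]), timestamp = t,
                 frameId = paste0("f", t))
  expect_error(FrameSequence(list(fr(0), fr(0))), "strictly increasing")
  expect_error(FrameSequence(list(fr(0), ThermalFrame(matrix(30, 3, 4),
                                                      timestamp = 10))),
               "constant")
  expect_error(FrameSequence(list(fr(0), fr(10), fr(25)), cadence = 10),
               "cadence")
  expect_s4_class(FrameSequence(list(fr(0), fr(10), fr(20)), cadence = 10),
                  "FrameSequence")
})

test_that("sequences round-trip through manifest, frames and ROI config", {
  fr <- lapply(c(0, 10, 20), function(t)
    ThermalFrame(matrix(28 + t / 100, 4, 5), timestamp = t,
                 frameId = sprintf("f%02d", t)))
  rois <- list(
    RegionOfInterest("plantA", "rectangle", c(0, 0, 4, 2), "plant",
                     anchor = c(2, 1)),
    RegionOfInterest("air", "point_cursor", c(0, 2, 3, 5), "air_cursor"))
  s <- FrameSequence(fr, cadence = 10, rois = rois,
                     dayNightSchedule = data.frame(lightsOnMin = 0,
                                                   lightsOffMin = 960))
  d <- withr::local_tempdir()
  manifest <- writeSequence(s, d)
  s2 <- readSequence(manifest, file.path(d, "rois.yaml"))
  expect_equal(length(s2), 3L)
  expect_equal(temperatures(s2[[2]]), temperatures(s[[2]]))
  expect_equal(vapply(frames(s2), timestamp, numeric(1)), c(0, 10, 20))
  expect_equal(cadence(s2), 10)
  a <- rois(s2)[[1]]
  expect_equal(a@anchor, c(2, 1))
  expect_equal(rois(s2)[[2]]@role, "air_cursor")

  # missing frame file is reported by frame id
  file.remove(file.path(d, "f10.csv"))
  expect_error(readSequence(manifest, file.path(d, "rois.yaml")), "f10")
})
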