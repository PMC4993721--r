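# Segmentation, principal-axis angle measurement, turgor mapping.

test_that("segmentation recovers the exact ground-truth mask pre-stress", {
  gen <- smallScene()
  cfg <- gen$truth@config
  tm <- 1440 + 600
  i <- which(vapply(frames(gen$sequence), timestamp, numeric(1)) == tm)
  roles <- vapply(rois(gen$sequence), function(r) r@role, character(1))
  plantRois <- rois(gen$sequence)[roles == "plant"]
  for (r in plantRois) {
    got <- segmentPlant(gen$sequence[[i]], r, cfg@dayAirTemp)
    want <- trueLeafMask(gen$truth, tm, r@name)
    expect_equal(sortMask(got), sortMask(unname(want)),
                 ignore_attr = TRUE)
  }
})

test_that("zero thermal contrast yields an empty mask flagged small_mask", {
  f <- uniformFrame(32, c(20, 20))
  roi <- RegionOfInterest("p", "rectangle", c(0, 0, 20, 20), "plant")
  mask <- segmentPlant(f, roi, airTemp = 32)
  expect_equal(nrow(mask), 0L)
  est <- estimateLeafAngle(mask, c(10, 10))
  expect_true(is.na(est$angle))
  expect_equal(est$quality, "small_mask")
})

test_that("only the largest 8-connected component is retained", {
  m <- matrix(30, 12, 12)
  big <- as.matrix(expand.grid(row = 2:4, col = 2:4))      # 9 px
  small <- as.matrix(expand.grid(row = 8:9, col = 8:9))    # 4 px
  m[big] <- 27; m[small] <- 27
  f <- ThermalFrame(m)
  roi <- RegionOfInterest("p", "rectangle", c(0, 0, 12, 12), "plant")
  mask <- segmentPlant(f, roi, airTemp = 30)
  expect_equal(nrow(mask), 9L)
  expect_equal(sortMask(mask), sortMask(unname(big)), ignore_attr = TRUE)

  # diagonal adjacency joins components (8-connectivity)
  m2 <- matrix(30, 12, 12)
  diagPix <- cbind(row = 2:6, col = 2:6)
  m2[diagPix] <- 27
  mask2 <- segmentPlant(ThermalFrame(m2), roi, airTemp = 30)
  expect_equal(nrow(mask2), 5L)
})

test_that("segmentation is invariant to a common temperature offset", {
  gen <- smallScene()
  cfg <- gen$truth@config
  tm <- 1440 + 600
  i <- which(vapply(frames(gen$sequence), timestamp, numeric(1)) == tm)
  roles <- vapply(rois(gen$sequence), function(r) r@role, character(1))
  r <- rois(gen$sequence)[roles == "plant"][[1]]
  f <- gen$sequence[[i]]
  shifted <- ThermalFrame(temperatures(f) + 2, timestamp = timestamp(f))
  expect_equal(sortMask(segmentPlant(f, r, cfg@dayAirTemp)),
               sortMask(segmentPlant(shifted, r, cfg@dayAirTemp + 2)))
})

test_that("render-estimate round trip is within 1 degree at 7 angles", {
  for (a in c(0, 15, 30, 45, 60, 75, 90)) {
    m <- renderLeafMask(a, c(60, 50), 35, 9, c(120, 160), side = -1)
    expect_gte(nrow(m), 200)
    est <- estimateLeafAngle(m, c(60, 50))
    expect_equal(est$quality, "ok")
    expect_lt(abs(est$angle - a), 1)
  }
})

test_that("isotropic masks are flagged ambiguous", {
  disc <- as.matrix(expand.grid(row = 1:20, col = 1:20))
  ctr <- c(10.5, 10.5)
  disc <- disc[(disc[, 1] - ctr[1])^2 + (disc[, 2] - ctr[2])^2 <= 81, ]
  est <- estimateLeafAngle(disc, c(20, 10))
  expect_equal(est$quality, "ambiguous_axis")
  expect_true(is.na(est$angle))
})

test_that("angle-to-turgor mapping is the linear protractor convention", {
  expect_equal(angleToTurgor(90), 100)
  expect_equal(angleToTurgor(0), 0)
  expect_equal(angleToTurgor(45), 50)
  expect_equal(angleToTurgor(110), 100)    # saturates beyond horizontal
  expect_error(angleToTurgor(-5), "non-negative")

  ang <- seq(0, 120, by = 0.5)
  tu <- angleToTurgor(ang)
  expect_true(all(diff(tu) >= 0))                      # monotone
  onScale <- ang <= 90
  expect_equal(tu[onScale], ang[onScale] / 90 * 100)   # exactly linear
})
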