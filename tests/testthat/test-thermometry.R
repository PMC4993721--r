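# Leaf/air temperature assignment, apical correction, hourly aggregation.

test_that("assignment follows the pre/post-stress interpretation switch", {
  # transpiring canopy: minimum is leaf temperature
  r1 <- data.frame(time = 0, plant = "p", roiMin = 29.0, roiMax = 32.5,
                   airTemp = 32.0)
  a1 <- assignLeafTemperature(r1)
  expect_equal(a1$mode, "min_is_leaf")
  expect_equal(a1$leafTemp, 29.0)

  # collapse towards equilibrium then a maximum above air: switch fires
  r2 <- data.frame(time = c(0, 10, 20),
                   plant = "p",
                   roiMin = c(29.0, 31.8, 31.9),
                   roiMax = c(32.5, 32.4, 32.6),
                   airTemp = 32.0)
  a2 <- assignLeafTemperature(r2)
  expect_equal(a2$mode, c("min_is_leaf", "max_is_leaf", "max_is_leaf"))
  expect_equal(a2$leafTemp, c(29.0, 32.4, 32.6))

  # degenerate uniform ROI: value independent of mode
  r3 <- data.frame(time = 0, plant = "p", roiMin = 31.0, roiMax = 31.0,
                   airTemp = 31.2)
  expect_equal(assignLeafTemperature(r3)$leafTemp, 31.0)
})

test_that("hysteresis blocks switch-back within 60 minutes", {
  r <- data.frame(time = c(0, 10, 40, 80),
                  plant = "p",
                  roiMin = c(31.9, 31.9, 28.5, 28.5),  # transpiring again at t=40
                  roiMax = c(32.5, 32.5, 32.0, 32.0),
                  airTemp = 32.0)
  a <- assignLeafTemperature(r)
  # switch to max at t=0; attempt at t=40 is inside the dead time
  expect_equal(a$mode, c("max_is_leaf", "max_is_leaf", "max_is_leaf",
                         "min_is_leaf"))
})

test_that("apical interference correction suppresses point outliers", {
  vals <- c(rep(30.0, 100), 35.0)
  hi <- apicalCorrect(vals, "max_is_leaf")
  expect_equal(hi$value, 30.0)
  expect_true(hi$corrected)

  lo <- apicalCorrect(c(rep(30.0, 100), 25.0), "min_is_leaf")
  expect_equal(lo$value, 30.0)
  expect_true(lo$corrected)

  clean <- apicalCorrect(rep(30.0, 100), "max_is_leaf")
  expect_equal(clean$value, 30.0)
  expect_false(clean$corrected)

  few <- apicalCorrect(c(rep(30.0, 10), 35.0), "max_is_leaf")
  expect_equal(few$value, 35.0)   # too few pixels: raw extreme kept
  expect_false(few$corrected)
})

test_that("hourly aggregation averages daytime frames and flags gaps", {
  sched <- data.frame(lightsOnMin = 0, lightsOffMin = 600)  # 10-h day
  tm <- seq(0, 1430, by = 10)
  s <- data.frame(plant = "p", time = tm,
                  leafTemp = 28 + tm / 1000, turgor = 50)
  h <- hourlyAggregate(s, sched)
  expect_equal(nrow(h), 10L)            # exactly 10 daytime hourly values
  expect_false(any(h$partial))
  # linear signal: hourly mean equals the value at the reported mid time
  expect_equal(h$leafTemp, 28 + h$timeMid / 1000, tolerance = 1e-12)

  # the worked example: six frames 28,28,29,29,30,30 average to 29
  s6 <- data.frame(plant = "p", time = seq(0, 50, 10),
                   leafTemp = c(28, 28, 29, 29, 30, 30), turgor = NA_real_)
  h6 <- hourlyAggregate(s6, data.frame(lightsOnMin = 0, lightsOffMin = 60))
  expect_equal(h6$leafTemp, 29.0)

  # constant series aggregates to the same constant
  sc <- data.frame(plant = "p", time = tm, leafTemp = 30.5, turgor = 42)
  hc <- hourlyAggregate(sc, sched)
  expect_true(all(hc$leafTemp == 30.5))
  expect_true(all(hc$turgor == 42))

  # a gap leaves an empty hour: NA and flagged
  sg <- s[s$time < 120 | s$time >= 180, ]
  hg <- hourlyAggregate(sg, sched)
  expect_true(is.na(hg$leafTemp[hg$hour == 2]))
  expect_true(hg$partial[hg$hour == 2])
})

test_that("extraction equals ground truth on the noiseless scene, both modes", {
  gen <- smallScene()
  series <- smallSeries()
  truth <- groundTruth(gen$truth)
  m <- merge(series, truth[, c("time", "plant", "leafTemp", "airTemp")],
             by = c("time", "plant"), suffixes = c("", ".true"))
  expect_equal(nrow(m), nrow(series))
  expect_equal(m$leafTemp, m$leafTemp.true, tolerance = 1e-12)
  expect_equal(m$airTemp, m$airTemp.true, tolerance = 1e-12)
  expect_equal(m$delta, m$leafTemp - m$airTemp, tolerance = 1e-9)

  # interpretation switch fires exactly once for the wilting control,
  # never for the treated plant
  for (p in c("control", "treated")) {
    sp <- m[m$plant == p, ]
    sp <- sp[order(sp$time), ]
    flips <- sum(sp$mode[-1] != sp$mode[-nrow(sp)])
    expect_equal(flips, if (p == "control") 1L else 0L)
  }
})
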