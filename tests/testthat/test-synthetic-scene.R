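# Ground-truthed scene generation.

test_that("noiseless pre-stress frames render leaf pixels at air minus offset", {
  gen <- smallScene()
  cfg <- gen$truth@config
  # a Day-2 daytime frame, clear of the Day-1 relaxation transient
  tm <- 1440 + 600
  i <- which(vapply(frames(gen$sequence), timestamp, numeric(1)) == tm)
  m <- temperatures(gen$sequence[[i]])
  for (p in c("control", "treated")) {
    mask <- trueLeafMask(gen$truth, tm, p)
    expect_true(all(m[mask] == cfg@dayAirTemp - cfg@leafAirOffsetPrestress))
  }
  # background and air cursor sit exactly at air temperature
  roles <- vapply(rois(gen$sequence), function(r) r@role, character(1))
  cur <- rois(gen$sequence)[[which(roles == "air_cursor")]]
  expect_equal(roiExtract(gen$sequence[[i]], cur), rep(cfg@dayAirTemp, 9))
})

test_that("post-onset ground truth follows the configured kinetics exactly", {
  k <- AsymptoticParams(31.83, 4.0, 0.523)
  cfg <- smallScenarioConfig(controlKinetics = k)
  onset <- wiltOnsetMinutes(cfg)
  h <- seq(0, 8, 0.5)
  expect_equal(trueLeafTemp(cfg, onset + h * 60, "control"),
               asymValue(h, k), tolerance = 1e-12)
  # at 8 h the asymptote is approached within 0.1 degC
  expect_lt(abs(trueLeafTemp(cfg, onset + 480, "control") - 31.83), 0.1)

  cfgT <- smallScenarioConfig()
  expect_equal(trueLeafTemp(cfgT, onset + h * 60, "treated"),
               asymValue(h, cfgT@treatedKinetics), tolerance = 1e-12)
})

test_that("pre-stress and recovery leaf-air deficits match the scenario", {
  cfg <- smallScenarioConfig()
  # Day-2 daytime: delta equals the configured pre-stress offset
  tms <- 1440 + seq(120, 900, 60)
  d <- trueLeafTemp(cfg, tms, "control") - trueAirTemp(cfg, tms)
  expect_true(all(d == -cfg@leafAirOffsetPrestress))
  # Day-5 treated after recovery: 2-3 degC below air
  tr <- rewaterMin <- (cfg@nDays - 1) * 1440 +
    (cfg@rewaterHoursAfterLight + cfg@recoveryHours) * 60
  dd <- trueLeafTemp(cfg, tr + c(0, 60, 120), "treated") -
    trueAirTemp(cfg, tr + c(0, 60, 120))
  expect_true(all(dd <= -2 & dd >= -3))
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- scenarioConfig(nDays = 1, wiltDay = 1, cadence = 120,
                        frameShape = c(60, 80),
                        leafLength = 16, leafWidth = 5, noiseSd = 0.1,
                        seed = 11)
  a <- generateSequence(cfg)
  b <- generateSequence(cfg)
  expect_identical(lapply(frames(a$sequence), temperatures),
                   lapply(frames(b$sequence), temperatures))
  cfg@seed <- 12
  c3 <- generateSequence(cfg)
  expect_false(identical(temperatures(a$sequence[[1]]),
                         temperatures(c3$sequence[[1]])))
})

test_that("rendered leaves have the geometry their angle implies", {
  shape <- c(120, 160)
  horiz <- renderLeafMask(90, c(60, 50), 35, 9, shape)
  expect_lte(diff(range(horiz[, 1])), 9)        # spans rows only by width
  expect_gt(diff(range(horiz[, 2])), 30)
  hang <- renderLeafMask(0, c(60, 50), 35, 9, shape)
  expect_lte(diff(range(hang[, 2])), 9)
  expect_gt(diff(range(hang[, 1])), 30)

  est <- estimateLeafAngle(renderLeafMask(45, c(60, 50), 35, 9, shape),
                           c(60, 50))
  expect_lt(abs(est$angle - 45), 1)

  expect_error(renderLeafMask(130, c(60, 50), 35, 9, shape), "\\[0, 120\\]")
  expect_error(renderLeafMask(0, c(110, 50), 35, 9, shape), "clipped")
})

test_that("degenerate scenarios are rejected", {
  expect_error(generateSequence(smallScenarioConfig(leafLength = 60)),
               "cannot fit")
  expect_error(scenarioConfig(photoperiod = c(16, 9)), "24")
  expect_error(scenarioConfig(noiseSd = -1), "non-negative")
})

test_that("detected onset on noiseless control data matches ground truth", {
  series <- smallSeries()
  gen <- smallScene()
  res <- detectWiltingOnset(series[series$plant == "control", ],
                            schedule = daySchedule(gen$sequence))
  expect_lte(abs(onsetTime(res) - wiltOnset(gen$truth)[["control"]]),
             cadence(gen$sequence))
})
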