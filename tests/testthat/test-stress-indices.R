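# CWSI, Ig and conductance calibration.

test_that("CWSI satisfies its defining identities", {
  expect_equal(as.numeric(cwsi(29, 29, 32)), 0)
  expect_equal(as.numeric(cwsi(32, 29, 32)), 1)
  expect_equal(as.numeric(cwsi(30.5, 29, 32)), 0.5)
  expect_error(cwsi(30, 32, 32), "degenerate")

  v <- cwsi(c(28, 33), 29, 32)
  expect_equal(attr(v, "outOfRange"), c(TRUE, TRUE))
  expect_lt(v[1], 0)   # unclamped
  expect_gt(v[2], 1)
})

test_that("CWSI complement identity holds to 1e-12 on a random grid", {
  set.seed(42)
  tNws <- 29; tMax <- 32
  tc <- runif(1000, 26, 35)
  lhs <- as.numeric(cwsi(tc, tNws, tMax)) + (tMax - tc) / (tMax - tNws)
  expect_lt(max(abs(lhs - 1)), 1e-12)
  # strictly increasing in canopy temperature
  grid <- sort(tc)
  expect_true(all(diff(as.numeric(cwsi(grid, tNws, tMax))) > 0))
})

test_that("Ig satisfies its identities and diverges at the wet reference", {
  expect_equal(igIndex(32, 32, 28.5), 0)
  expect_equal(igIndex(30.25, 32, 28.5), 1)   # equidistant references
  expect_error(igIndex(28.5, 32, 28.5), "tWet")
  expect_error(igIndex(30, 28, 29), "degenerate")

  # strictly decreasing in leaf temperature, growing without bound
  tl <- seq(32, 28.51, length.out = 100)
  ig <- igIndex(tl, 32, 28.5)
  expect_true(all(diff(ig) > 0))   # tl decreases along the grid
  expect_gt(ig[100], 100)
})

test_that("conductance calibration is a positive linear scaling", {
  expect_equal(stomatalConductance(0, 0.01), 0)
  expect_equal(stomatalConductance(1, 0.01), 0.01)
  ig <- c(0.3, 0.8, 1.7)
  expect_equal(stomatalConductance(2 * ig, 0.01),
               2 * stomatalConductance(ig, 0.01))
  expect_error(stomatalConductance(1, 0), "positive")
})

test_that("control CWSI rises monotonically from ~0 to ~1 across wilting", {
  series <- smallSeries()
  gen <- smallScene()
  sched <- daySchedule(gen$sequence)
  refs <- referencesFromSeries(series, sched)
  ctrl <- series[series$plant == "control", ]
  h <- hourlyAggregate(ctrl, sched)
  d3 <- h[h$day == 3 & !is.na(h$leafTemp), ]
  cw <- as.numeric(cwsi(d3$leafTemp, refs$tNws, refs$tMax))
  expect_lt(abs(cw[1]), 0.05)
  expect_gt(cw[length(cw)], 0.9)
  expect_true(all(diff(cw) > -1e-9))
})

test_that("index table guards the Ig domain and carries flags", {
  s <- data.frame(time = c(0, 10, 20), plant = "p", treatment = "control",
                  leafTemp = c(28.0, 30.0, 33.5), airTemp = 33)
  refs <- list(tNws = 29, tMax = 33, tDry = 33, tWet = 29)
  tab <- indexTable(s, refs, G = 0.01)
  expect_true(is.na(tab$ig[1]))              # leaf below wet reference
  expect_equal(tab$ig[2], (33 - 30) / (30 - 29))
  expect_equal(tab$gs[2], 0.01 * tab$ig[2])
  expect_equal(tab$cwsiFlag, c(TRUE, FALSE, TRUE))
  expect_equal(tab$delta, s$leafTemp - 33)
})
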