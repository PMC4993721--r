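# Onset detection, asymptotic fitting, shape classification, phase
# clustering and the turgor-temperature relationship.

ctrlTheta <- c(31.83, 4.0, 0.523)
trtTheta <- c(82.81, 55.1, 0.0098)

test_that("noiseless generate-fit round trips recover both parameter sets", {
  x <- seq(0, 8, 0.5)
  for (p in list(ctrlTheta, trtTheta)) {
    fit <- fitAsymptotic(x, asymValue(x, p))
    expect_true(converged(fit))
    expect_lt(max(abs(theta(fit) - p) / p), 1e-3)
  }
  # model value at X = 0 is theta1 - theta2
  expect_equal(asymValue(0, ctrlTheta), 27.83)
  # the near-linear set is flagged as ill-conditioned
  fitT <- fitAsymptotic(x, asymValue(x, trtTheta))
  expect_true(fitT@conditioningWarning)
})

test_that("the fitter agrees with an independent NLS implementation", {
  skip_if_not_installed("minpack.lm")
  set.seed(99)
  x <- seq(0, 8, 0.5)
  y <- asymValue(x, ctrlTheta) + rnorm(length(x), 0, 0.1)
  mine <- fitAsymptotic(x, y)
  ref <- minpack.lm::nlsLM(
    y ~ t1 - t2 * exp(-t3 * x),
    start = list(t1 = max(y), t2 = diff(range(y)), t3 = 1 / diff(range(x))),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14))
  expect_equal(unname(theta(mine)), unname(coef(ref)), tolerance = 1e-5)
  expect_equal(mine@rss, sum(residuals(ref)^2), tolerance = 1e-8)
  expect_equal(unname(mine@se),
               unname(summary(ref)$coefficients[, "Std. Error"]),
               tolerance = 1e-4)
})

test_that("fitting is invariant to re-anchored time shifts", {
  x <- seq(0, 8, 0.5)
  y <- asymValue(x, ctrlTheta)
  shifted <- (x + 3.25) - 3.25   # shift then re-zero the onset
  expect_equal(theta(fitAsymptotic(shifted, y)), theta(fitAsymptotic(x, y)))
})

test_that("fit preconditions are enforced", {
  expect_error(fitAsymptotic(0:3, c(28, 29, 30, 30.5)), "at least 5")
  expect_error(fitAsymptotic(c(0, 1, 1, 2, 3), rep(30, 5)), "increasing")
  expect_error(fitAsymptotic(c(-1, 0, 1, 2, 3), rep(30, 5)), "non-negative")
})

test_that("theta1 recovery stays within 0.2 degC under sensor noise", {
  set.seed(2024)
  x <- seq(0, 8, 0.5)
  mu <- asymValue(x, ctrlTheta)
  err <- replicate(50, {
    fit <- fitAsymptotic(x, mu + rnorm(length(x), 0, 0.1))
    abs(theta(fit)[["theta1"]] - ctrlTheta[1])
  })
  expect_lt(median(err), 0.2)
})

test_that("shape classification separates asymptotic from near-linear", {
  expect_equal(classifyResponseShape(AsymptoticParams(31.83, 4, 0.523), 8),
               "asymptotic")
  expect_equal(classifyResponseShape(AsymptoticParams(82.81, 55.1, 0.0098), 8),
               "near_linear")
  # exclusive boundary: theta3 * horizon == 0.5 is asymptotic
  expect_equal(classifyResponseShape(AsymptoticParams(30, 3, 0.0625), 8),
               "asymptotic")
  # monotone in theta3: once asymptotic, larger rates stay asymptotic
  cls <- vapply(c(0.01, 0.05, 0.0625, 0.1, 0.5, 1),
                function(k) classifyResponseShape(AsymptoticParams(30, 3, k), 8),
                character(1))
  expect_true(all(diff(cls == "asymptotic") >= 0))
})

test_that("onset detection fires on wilt signatures and only on them", {
  tm <- seq(0, 600, 10)
  # constant turgor, clearly transpiring: no onset
  flat <- data.frame(plant = "p", time = tm, turgor = 60, delta = -3)
  expect_true(is.na(onsetTime(detectWiltingOnset(flat))))

  # single-frame collapse: onset at the step
  stepT <- ifelse(tm < 300, 60, 5)
  stp <- data.frame(plant = "p", time = tm, turgor = stepT, delta = -3)
  res <- detectWiltingOnset(stp)
  expect_lte(abs(onsetTime(res) - 300), 10)

  # gradual wilt at 20 %/h for two hours
  wilt <- pmax(60 - pmax(tm - 240, 0) / 60 * 20, 5)
  grd <- detectWiltingOnset(data.frame(plant = "p", time = tm,
                                       turgor = wilt, delta = -3))
  expect_lte(abs(onsetTime(grd) - 240), 20)

  # fallback: no turgor, delta rising above -1 degC and staying there
  dl <- data.frame(plant = "p", time = tm, turgor = NA_real_,
                   delta = ifelse(tm < 400, -3, -0.2))
  expect_equal(onsetTime(detectWiltingOnset(dl)), 400)

  expect_error(detectWiltingOnset(flat[1:3, ]), "insufficient")
})

test_that("phase clustering labels the analysis window around hour zero", {
  ph <- clusterPhases(c(-5, -2, 0, 3, 7))
  expect_equal(ph$phase, c(NA, "before_wilt", "after_wilt", "after_wilt", NA))
  expect_equal(ph$excluded, c(TRUE, FALSE, FALSE, FALSE, TRUE))
})

test_that("lowess reproduces exactly linear turgor-temperature data", {
  set.seed(5)
  temp <- runif(60, 28.5, 31)
  turg <- 320 - 10 * temp
  rel <- turgorTemperatureRelation(turg, temp)
  expect_lt(max(abs(rel$curves$smooth - (320 - 10 * rel$curves$temp))), 1e-6)
  expect_equal(rel$slopes$slope, -10, tolerance = 1e-10)
})

test_that("slope difference between groups is detected at stated effect size", {
  set.seed(31)
  n <- 40
  t1 <- runif(n, 28.5, 31); t2 <- runif(n, 28.5, 31)
  y1 <- 300 - 8 * t1 + rnorm(n, 0, 3)
  y2 <- 650 - 20 * t2 + rnorm(n, 0, 3)
  rel <- turgorTemperatureRelation(c(y1, y2), c(t1, t2),
                                   group = rep(c("a", "b"), each = n))
  expect_lt(rel$slopeDiffP, 0.05)
  expect_true(all(rel$slopes$slope < 0))
  expect_error(turgorTemperatureRelation(y1[1:5], t1[1:5]), "insufficient")
})

test_that("synthetic Day-3 turgor-temperature slopes are negative for both", {
  series <- smallSeries()
  d3 <- series[series$time >= 2880 & series$time < 4320 &
                 !is.na(series$turgor), ]
  rel <- turgorTemperatureRelation(d3$turgor, d3$leafTemp,
                                   group = d3$plant)
  expect_true(all(rel$slopes$slope < 0))
})
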