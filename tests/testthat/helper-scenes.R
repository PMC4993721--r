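# Shared fixtures: a small noiseless scene generated once per test run.

.sceneCache <- new.env(parent = emptyenv())

smallScenarioConfig <- function(frameShape = c(60, 80), leafLength = 16,
                                leafWidth = 5, noiseSd = 0, ...) {
  scenarioConfig(frameShape = frameShape, leafLength = leafLength,
                 leafWidth = leafWidth, noiseSd = noiseSd, ...)
}

smallScene <- function() {
  if (is.null(.sceneCache$scene))
    .sceneCache$scene <- generateSequence(smallScenarioConfig())
  .sceneCache$scene
}

smallSeries <- function() {
  if (is.null(.sceneCache$series)) {
    gen <- smallScene()
    assigned <- assignLeafTemperature(extractReadings(gen$sequence))
    angles <- measureAngles(gen$sequence)
    .sceneCache$series <- plantTimeSeries(assigned, angles)
  }
  .sceneCache$series
}

uniformFrame <- function(value = 30, dims = c(10, 10), ...)
  ThermalFrame(matrix(value, dims[1], dims[2]), ...)

sortMask <- function(m) m[order(m[, 1], m[, 2]), , drop = FALSE]
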