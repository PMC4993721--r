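---
title: "Thermal imaging analysis of plant drought stress: models and methods"
author: "thermoleaf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermal imaging analysis of plant drought stress: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoleaf)
```

## The measurement problem

A transpiring leaf is cooled by evaporation through its stomata and
typically sits a few degrees Celsius below air temperature; when soil
water runs out and stomata close, evaporative cooling fails and the leaf
relaxes towards — and, under lamps, slightly past — thermal equilibrium
with the air. Radiometric thermal imaging therefore turns leaf temperature
into a non-contact early indicator of drought stress, and the *rate* and
*shape* of the post-wilting temperature relaxation into a quantitative
phenotype that distinguishes a passively equilibrating canopy from one
still actively controlling its stomata.

`thermoleaf` implements that analysis as a tested pipeline: frame and ROI
containers, leaf/air temperature extraction, leaf-angle ("digital
protractor") and turgor measurement, the CWSI and Ig stress indices,
wilting-onset detection and asymptotic stress-kinetics regression — plus a
synthetic scene generator with exact ground truth, so every stage is
verifiable without camera data.

## Models

### Asymptotic stress kinetics

Post-onset leaf temperature is modelled as a first-order relaxation

$$Y = \theta_1 - \theta_2\, e^{-\theta_3 X} + \varepsilon,$$

with $Y$ leaf temperature (°C), $X$ time since wilting onset (h),
$\theta_1$ the equilibrium temperature (the asymptote), $\theta_2$ the
relaxation amplitude, $\theta_3$ the rate (h⁻¹), and i.i.d. Gaussian
errors. `fitAsymptotic()` estimates the parameters by damped Gauss–Newton
(Levenberg–Marquardt) least squares with an analytic Jacobian:

* default start: $\theta_1 = \max(y)$, $\theta_2 = \max(y) - \min(y)$,
  $\theta_3 = 1/\mathrm{range}(x)$;
* convergence when the relative RSS change falls below $10^{-10}$ or the
  gradient norm below $10^{-8}$, at most 500 iterations;
* standard errors from the Jacobian cross-product at the optimum;
* residual checks: Shapiro–Wilk normality and lag-1 Ljung–Box
  independence, reported as p-values with pass flags at 0.05.

The near-linear regime ($\theta_3 \to 0$) is badly conditioned in this
parametrization: $\theta_1$ and $\theta_2$ become almost collinear. When
the default-start iteration stalls, the fitter restarts from a
variable-projection profile (for fixed $\theta_3$ the model is linear in
$\theta_1, \theta_2$, so the profiled RSS is minimized over
$\log\theta_3$ by Brent search) and polishes with the same LM iteration.
Such fits carry a conditioning warning and may report `NA` standard
errors; the parameter estimates themselves remain well defined because
the data constrain the fitted curve, not the individual coordinates.

`classifyResponseShape()` calls a fit **near-linear** when
$\theta_3 \cdot \mathrm{horizon} < 0.5$: over the observation window the
exponential is then sampled on so short an arc that the curve is
indistinguishable from a straight line. The boundary (product exactly
0.5) counts as asymptotic. This operationalizes the qualitative
asymptotic-versus-linear distinction between a failed and a functioning
stomatal response.

### Stress indices

With reference temperatures for a fully transpiring
($T_{nws}$/$T_{wet}$) and a non-transpiring ($T_{max}$/$T_{dry}$) canopy,

$$\mathrm{CWSI} = \frac{T_{canopy} - T_{nws}}{T_{max} - T_{nws}}, \qquad
I_g = \frac{T_{dry} - T_{leaf}}{T_{leaf} - T_{wet}} = g_s / G.$$

CWSI runs from 0 (well-watered) to 1 (dry); out-of-range values are
*flagged, not clamped*, because they diagnose references that fail to
bracket the observation. Ig is undefined at or below the wet reference
(the package raises a domain error rather than returning a signed
surprise) and converts to stomatal conductance only when a calibration
slope `G` is supplied; `G` has no default because it must come from an
independent calibration. The proportionality $I_g \propto g_s$ assumes
constant boundary-layer conditions; the package exposes but cannot
validate that physical assumption.

Reference temperatures must normally be supplied. For self-contained
demonstration runs `referencesFromSeries()` derives them by convention —
dry references from mean daytime air temperature, wet references from
mean Day-1 daytime leaf temperature — which is documented as a
convention, not a measurement protocol.

### Leaf angle and turgor

Leaf angle is measured against the downward vertical stem axis: 0° is a
leaf hanging along the stem (wilted), 90° horizontal (full turgor).
`segmentPlant()` selects ROI pixels whose temperature differs from air by
more than a contrast threshold (default 0.8 °C, either sign — transpiring
leaves are cooler, wilted sunlit leaves warmer) and keeps the largest
8-connected component; being contrast-based, it is invariant to a common
temperature offset. `estimateLeafAngle()` replaces an interactive
protractor with the leading eigenvector of the pixel-coordinate
covariance, oriented away from the stem anchor — deterministic and
testable. Turgor is the linear index
$\mathrm{clamp}(\mathrm{angle}/90 \times 100,\ 0,\ 100)$ %; angles above
90° (transient hyper-erect leaves) are permitted up to 120° but the index
saturates at 100 %, since the mapping is only defined on [0°, 90°].

A real plant has many leaves; the package measures the principal axis of
the whole segmented mask, which can differ from per-leaf manual
protractor readings. Masks smaller than 30 pixels (`small_mask`) or with
a leading/trailing eigenvalue ratio below 1.2 (`ambiguous_axis`) report
no angle.

### Temperature extraction and the interpretation switch

Before wilting the ROI *minimum* is leaf temperature (leaves are the
coolest objects in the region) and the maximum reflects ambient; after a
wilted canopy equilibrates and warms past air temperature, the *maximum*
is the leaf/stem temperature. `assignLeafTemperature()` makes that switch
explicit and automatic: a plant starts in `min_is_leaf` mode and switches
to `max_is_leaf` once the ROI minimum no longer sits more than 0.5 °C
below air *and* the maximum exceeds air; switches in either direction are
blocked for 60 min after the last one. The margin-plus-hysteresis rule
exists because near equilibrium the two extremes straddle air temperature
within sensor noise, and a memoryless rule would chatter. Air temperature
is the mean of the 3×3-pixel air cursor placed between the plants.

Raw ROI extremes are vulnerable to a wilting apical point bending into
the ROI. `apicalCorrect()` replaces them with robust extremes — the 2nd
(min mode) or 98th (max mode) percentile of the ROI pixels, given at
least 20 pixels — flagging the reading when raw and robust differ by more
than 0.3 °C. This replaces a manual, eyeballed correction with a
deterministic rule.

`hourlyAggregate()` averages each daytime hour (six frames at the 10-min
cadence), flags partial hours at light transitions and reports the mean
frame time of each bin, so linear signals aggregate exactly to their
value at the reported time.

### Wilting-onset detection

The kinetic analysis is anchored at "hour 0", the initiation of wilting.
No algorithm for that anchor exists in the field protocol, so
`detectWiltingOnset()` defines one: the first daytime instant whose
centred finite-difference turgor drop rate exceeds 15 %/h *and* whose
mean forward drop over the next 30 min also exceeds it. The two-part
reading fires both on a sustained wilt (tens of %/h for over an hour) and
on a single-frame collapse, while rejecting isolated blips; restricting
candidates to daytime keeps the diurnal evening leaf-fold from
registering as wilt. The threshold sits well below a genuine wilt
signature (≈40 %/h in the reference scenario) and well above slow stress
drift (≈3 %/h). When no turgor signal is available, a fallback looks for
the leaf-air temperature difference first rising above −1 °C and staying
there — a canopy approaching thermal equilibrium.

### Turgor-temperature relationship

`turgorTemperatureRelation()` smooths turgor against leaf temperature
with LOWESS (tricube weights, span 0.5, 2 robustness iterations) inside a
28.5–31.0 °C analysis window, reports per-group OLS slopes over the same
window, and tests a two-group slope difference through the interaction
contrast of `turgor ~ temp * group`. The span is a package choice (the
field protocol names the smoother but no span) and is recorded in the
output; LOWESS reproduces exactly linear data exactly, which the tests
exploit as an oracle.

## The synthetic scenario

`scenarioConfig()` describes a five-day stress–recovery trial in a growth
chamber and `generateSequence()` renders it with exact closed-form ground
truth (leaf/air temperature, leaf angle, wilt-onset time, per-frame leaf
masks). Defaults, with their provenance:

* **Chamber**: 16:8 h photoperiod, air 27 °C at night rising to 33 °C
  under the lamps; frames every 10 min; pixel noise SD 0.1 °C (the
  sensor's temperature resolution); emissivity 0.95.
* **Pre-stress**: leaves 3.0 °C below air by day. At night the deficit is
  0.5 °C (stomata closed; a value the protocol leaves unstated). Day 1
  opens with a 2 °C warm transient relaxing with a 40-min time constant
  (settled within two hours) — the initial response to soil saturation;
  magnitude and duration are package choices.
* **Wilting**: the control collapses on Day 3 after 5.5 h of light; its
  leaf angle falls from 55° to 3° over 90 min, and its temperature
  follows the asymptotic model from the moment of onset.
* **Angles**: 55° by day, 20° at night (the protocol states only "low"),
  with 60-min rise/fold ramps placed just after lights-on and lights-off
  so the fold never mimics a daytime wilt.
* **Recovery**: re-watering 2 h after lights-on on the final day; the
  treated plant recovers over 2.5 h to a 2.5 °C deficit, the control
  stays at equilibrium.

The post-onset temperature kinetics deserve a note. The generator's
background pixels sit at air temperature, so the extraction oracle —
noiseless scenes must extract to ground truth *exactly*, through both
assignment modes, with the interpretation switch firing exactly once for
the control and never for the treated plant — forces two constraints on
the scene defaults: the wilted control's asymptote must lie *above* air
temperature (otherwise the ROI maximum is background, not leaf), and the
treated plant's deficit must stay outside both the switch margin
(0.5 °C) and the onset fallback threshold (1 °C). The default scene
therefore anchors the kinetics to its own chamber: control
$\theta = (33.8, 3.8, 0.523)$ — the published relaxation rate, asymptote
0.8 °C above air as for a non-transpiring sunlit canopy — and treated
$\theta = (52, 22, 0.0098)$ — the published near-linear rate, capped at
1.2 °C below air, with the amplitude chosen so the trajectory stays below
the cap throughout the 8-h fitting window. `controlKinetics` and
`treatedKinetics` accept any parameter set when a different scene is
wanted; the published parameter sets themselves are used verbatim in the
validation suite's generate-and-fit round trips.

What the generator does **not** emulate: radiative transfer and
convection, wind, 3-D plant architecture, per-leaflet motion, soil
moisture (the scenario drives temperature kinetics directly; no
soil-to-leaf coupling law is modelled), camera vignetting or drift. A
passing pipeline therefore demonstrates correctness of the *analysis* —
extraction, geometry, onset, fitting — under known truth, not robustness
to every artefact of chamber imaging.

## Numerical and interface conventions

* Pixel coordinates are 0-based, half-open `(row_min, col_min, row_max,
  col_max)` in ROI configurations, and 1-based `(row, col)` matrices in R
  code — stated once, enforced everywhere.
* Oval ROIs include pixels whose *centres* fall inside the ellipse
  inscribed in the bounding box; boundary-pixel behaviour of interactive
  tools is not defined, so this convention is ours.
* Temperature grids are stored as plain CSV (°C values, no header) or
  single-channel 32-bit float TIFF (pixel value = °C) with a JSON
  metadata sidecar; proprietary radiometric containers are out of scope.
  The float TIFF writer is built in because no installed R writer emits
  float samples; reading uses `tiff::readTIFF`, which handles them
  natively.
* Robust extremes use the default empirical quantile definition (type 7).
* Fits are invariant to uniform time shifts once the onset is re-zeroed;
  the pipeline always re-anchors before fitting.
* All pipeline artifacts are plain CSV/JSON; identical configuration and
  seed reproduce them byte for byte.

## Problem sizes in the validation suite

The test suite exercises the full default scene — five days at 10-min
cadence, 120 × 160-pixel frames, two plants (720 frames, 1 440
plant-frame readings) — for the end-to-end noiseless oracle, and a
60 × 80-pixel variant of the same scenario for module-level checks.
Stochastic checks use 200 replicates of the 17-point generate-and-fit
round trip at 0.1 °C noise and 200 replicates of the two-group
slope-difference simulation (n = 40 per group, slopes −8 and −20 %/°C,
noise SD 3 %). These sizes were chosen as the smallest that make the
deterministic oracles exhaustive and leave the stochastic checks with
comfortable margins.

## Known limitations

* Post-stress "leaf" temperature conflates leaf and stem pixels; the
  robust maximum is reported as leaf temperature.
* One angle per plant: the whole-mask principal axis, not per-leaf
  protractor readings.
* Reference temperatures for CWSI/Ig are a convention unless measured
  references are supplied; no energy-balance derivation is attempted.
* Angle measurement needs thermal contrast: near equilibrium (contrast
  below the segmentation threshold) angles are unmeasurable and reported
  as `small_mask`, so turgor has gaps precisely where the canopy is most
  stressed — matching the physics, but worth remembering when
  interpreting turgor series.
* The near-linear fit's standard errors are unreliable by construction
  (ill-conditioning); the conditioning warning should be heeded rather
  than the SEs quoted.
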