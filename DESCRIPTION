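Package: thermoleaf
Title: Thermal Imaging Analysis of Plant Drought Stress
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing time-lapse radiometric thermal images of
    plants under drought stress. Provides S4 containers for temperature
    frames, regions of interest and frame sequences; a ground-truthed
    synthetic scene generator emulating a five-day stress-recovery trial;
    leaf and air temperature extraction with a pre/post-wilting min/max
    interpretation switch and robust apical-interference correction;
    thermal segmentation, principal-axis leaf-angle measurement and a
    linear angle-to-turgor mapping; crop water stress index (CWSI) and
    index of relative stomatal conductance (Ig); wilting-onset detection;
    and asymptotic stress-kinetics regression by damped Levenberg-Marquardt
    least squares with residual diagnostics, including classification of
    asymptotic versus near-linear responses and locally weighted
    turgor-temperature relationship analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    minpack.lm,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
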