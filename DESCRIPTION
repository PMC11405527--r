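Package: wsci
Title: Waveform Structural Complexity of Forest Canopies from Lidar
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for measuring and modelling 3D forest canopy structural
    complexity at the scale of large lidar footprints. Computes the
    kernel-density grid entropy of point-cloud projections (canopy entropy,
    CE), simulates large-footprint waveforms and relative-height (RH)
    percentile profiles from airborne laser scanning point clouds, recovers
    footprint geolocation offsets by waveform correlation, and fits
    spatially cross-validated gradient-boosted models that predict the
    Waveform Structural Complexity Index (WSCI) from RH metrics. Prediction
    uncertainty is quantified with Mondrian split-conformal intervals, and
    per-prediction Shapley attributions are accumulated into lower, middle
    and upper waveform strata. Includes a seeded synthetic forest-stand
    generator for method evaluation and downstream analyses: grid
    aggregation, principal-component variance partition, and
    complexity-height scaling fits with outlier-robust regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    xgboost,
    MASS,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
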