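Package: forestpulse
Title: Forest-Cover Change, Thermal Condition and Criticality Indices
    from Multispectral Scenes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for monitoring forest cover and vegetation condition
    from multi-date multispectral imagery. Provides a synthetic
    Landsat-like scene generator with known ground truth, radiometric
    calibration and dark-object subtraction, Gaussian maximum-likelihood
    land-cover classification with majority filtering, stratified
    confusion-matrix accuracy assessment (overall, producer's and user's
    accuracy, kappa), change-detection cross-tabulation with gain/loss/net
    accounting, and the vegetation-thermal index chain: NDVI, proportion
    of vegetation, emissivity, brightness temperature, single-channel
    land surface temperature, the vegetation condition index with drought
    classes, and the environmental criticality index with
    histogram-equalization stretching, plus descriptive statistics and
    NDVI-LST regression.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'classes.R'
    'synthetic.R'
    'raster-io.R'
    'preprocess.R'
    'classify.R'
    'accuracy.R'
    'change.R'
    'indices.R'
    'thermal.R'
    'stats.R'
    'pipeline.R'
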