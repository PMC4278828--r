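Package: sdmuncert
Title: Monte Carlo Simulation of Uncertainty in Species Distribution Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates and communicates the impact of data-quality
    uncertainty on species distribution models projected to current and
    future climates. Implements error models for occurrence-record
    location error, spatially biased and random record loss, spatially
    correlated climate-surface measurement error, and training-data
    (model) variance; each Monte Carlo replicate refits a
    presence-background suitability model (a ridge-penalized logistic
    regression of the MaxEnt family) on the perturbed inputs, and the
    thresholded predictions are aggregated into spatially explicit
    presence-probability maps across a matrix of global climate model
    by emissions scenario futures. Includes derivation of six
    bioclimatic predictors from monthly climate grids, minimal GeoTIFF
    and ESRI ASCII raster input/output, and a synthetic-landscape
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    glmnet,
    geosphere,
    yaml,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
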