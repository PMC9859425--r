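Package: ecovuln
Title: Ecological Vulnerability Assessment with PCA-Weighted Indices,
    Spatial Autocorrelation, GeoDetector and CA-Markov Forecasting
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end toolkit for raster-based ecological vulnerability
    assessment built on the sensitivity-resilience-pressure (SRP) indicator
    framework. Provides polarity-aware min-max standardization of indicator
    stacks, a principal-component-weighted ecological vulnerability index
    (EVI), Jenks natural-breaks grading into five vulnerability classes,
    global and local Moran's I with permutation inference and LISA cluster
    maps, the geographical-detector q-statistic with factor and interaction
    detectors, and CA-Markov forecasting of vulnerability class maps with
    Kappa validation. A seeded synthetic-landscape generator produces
    spatially autocorrelated indicator stacks, clumped land-use maps and
    multi-epoch class series with recorded ground truth for recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
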