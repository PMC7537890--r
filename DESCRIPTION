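Package: esvdriver
Title: Socioeconomic Drivers of Ecosystem Service Value via a Neural Surrogate
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how socioeconomic factors drive ecosystem
    service value (ESV) on a regular spatial grid. Provides a seeded synthetic
    landscape generator (spatially autocorrelated land-use fraction fields,
    population, nighttime light and NDVI surfaces, and city-level statistical
    totals), dasymetric allocation of city totals onto grid units via
    weighting rasters, block aggregation to an analysis grid, a multilayer
    perceptron surrogate mapping 23 standardized factors to ESV with
    Nash-Sutcliffe / RSR evaluation, single-factor response curves with
    influence-intensity and curve-shape classification, two-factor coupling
    surfaces, and extraction of synergistic features from the penultimate
    network layer contrasted with principal component analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
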