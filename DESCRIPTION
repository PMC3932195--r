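Package: cdrisk
Title: Standard-Exceeding Probability Mapping for Soil Cadmium with
    Composite Quality Standards
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maps the probability that soil cadmium exceeds a composite
    environmental quality standard whose thresholds depend on soil pH
    interval and land-use type. Point samples of Cd and pH are modelled
    geostatistically (omnidirectional variograms, normal-score transform)
    and propagated to a regular grid by conditional sequential Gaussian
    simulation; per-cell exceedance probabilities are estimated as
    frequencies over the simulated realizations and thresholded into
    priority remediation masks. Includes a synthetic study-area generator
    (Gaussian random fields by circulant embedding, patchy categorical
    land use) so the full workflow is testable without field data, plus
    readers and writers for samples CSV, ESRI ASCII grids and JSON
    standard/configuration files, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
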