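Package: defolmap
Title: Rapid Assessment of Crop Defoliation from Aerial Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies insect-pest defoliation of field crops from
    aerial RGB orthomosaics and characterizes its spatial pattern.
    Implements green-pixel defoliation estimation with reference
    calibration and ground-survey damage categories, square-grid count
    aggregation, empirical semivariograms with exponential, spherical
    and Gaussian model fits and the degree-of-spatial-dependence
    statistic, Spatial Analysis by Distance IndicEs (SADIE) with an
    exact transportation solve and randomization inference, NDVI change
    detection for before/during/after satellite raster triplets, and an
    aerial-versus-ground survey time and cost model with breakeven
    analysis. Includes a synthetic-scene generator (Gaussian random
    fields with specified variogram structure, rendered RGB scenes, and
    NDVI triplets) so the whole pipeline is testable without imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    grDevices,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
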