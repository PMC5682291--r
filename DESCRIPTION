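Package: traitdiv
Title: Mapping Forest Functional Diversity from Remotely Sensed Trait Rasters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Taxonomy-free, spatially continuous mapping of forest functional
    diversity from co-registered trait rasters. Derives normalized
    morphological (canopy height, plant area index, foliage height diversity)
    and physiological (chlorophyll, carotenoid, equivalent water thickness)
    trait layers from canopy profiles and hyperspectral reflectance, computes
    functional richness (convex hull volume), divergence and evenness
    (minimum spanning tree) in circular moving windows across a schedule of
    spatial scales, builds diversity-area curves with power-law and
    logarithmic fits, and compares observed curves against random-shuffle and
    maximal under-dispersion null models. Includes a seedable synthetic
    landscape generator for end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
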