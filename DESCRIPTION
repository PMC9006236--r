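Package: nichebands
Title: Species Chromatograms for Multidimensional Ecological Niches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Projects the p-dimensional ecological niche of a species onto a
    two-dimensional coloured matrix (a "species chromatogram") by binning
    standardized environmental gradients into equidistant categories and
    recording the standardized maximal abundance per category. From a
    chromatogram the package quantifies the niche optimum and breadth along
    each environmental dimension, computes a symmetric hyperrectangle
    niche-overlap index D between species, and scans all combinations of
    dimensions for the most discriminant variable subsets. A beta-response
    pseudo-species simulator with known optima and amplitudes is included
    for validation, together with utilities for matching samples to gridded
    environmental fields and for light attenuation at depth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
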