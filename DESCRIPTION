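Package: gelsense
Title: Displacement Microscopy of Cell-Imparted Hydrogel Deformations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how adherent cells deform soft hydrogel
    substrates from time-lapse images of embedded fluorescent fiduciary
    beads. Provides a seeded synthetic-image generator with exact
    ground-truth displacement fields, a windowed normalized
    cross-correlation (digital image correlation) tracker with subpixel
    refinement and field smoothing, cumulative-displacement summary
    statistics (90th-percentile time courses with replicate spread and
    window averages), a confocal z-profile thickness estimator, and an
    axisymmetric finite-element model of the apparent stiffness a
    contracting circular patch experiences on an elastic layer of finite
    thickness with optional lateral constraint.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
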