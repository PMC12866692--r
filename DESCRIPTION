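Package: flockmetrics
Title: Quantifying Jamming, Unjamming and Flocking Transitions in
    Epithelial Monolayers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying collective cell migration in dense
    epithelial monolayers from time-lapse microscopy. Implements
    cross-correlation particle image velocimetry (PIV), kinematic
    observables (center-of-mass velocity, root-mean-square velocity,
    flocking order parameter), FFT-based spatial velocity correlation
    with stretched-exponential correlation-length fitting, radial
    distribution function neighbor thresholding and neighbor-exchange
    statistics, local density fields and fluctuation maps, 2D cell
    shape descriptors (aspect ratio, shape index), FRAP and wetting
    assay quantification, and a rule-based classifier that assigns one
    of four dynamic tissue states (jammed solid, disordered fluid,
    flocking fluid, flocking solid). A self-propelled-particle
    monolayer simulator generates labeled ground-truth data in all
    four regimes so every stage can be validated without experimental
    input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    tibble,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    knitr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
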