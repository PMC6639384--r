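Package: fadyn
Title: Focal Adhesion Protein Binding Dynamics from FRAP and Photoconversion Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the binding dynamics of focal adhesion (FA) proteins
    from fluorescence recovery after photobleaching (FRAP) and green-to-red
    photoconversion pulse-chase experiments. Provides a Monte Carlo
    reaction-diffusion simulator of fluorescent molecules diffusing in an
    ellipsoidal cell and binding at FA ellipsoids under a three-pool kinetic
    model (mobile, dynamically bound, stably bound), a database-fitting engine
    that estimates bound-fraction sizes and residence times from FRAP traces
    with quality-control filters and 1.5 x IQR iterative refitting, a
    photoconversion 'ratio view' image pipeline that maps stably bound protein
    within FAs via moment-preserving thresholding and particle analysis, FA
    classification by location and orientation relative to the ventral
    membrane edge, and synthetic-data generators with known ground truth for
    every input kind.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
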