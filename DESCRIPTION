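Package: ciliarray
Title: Detection and Organization Analysis of Ciliate Basal Bodies in 3D
    Fluorescence Stacks
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An automated image-analysis pipeline for cortical basal body
    (BB) organization in Tetrahymena thermophila. Detects diffraction-limited
    BB spots in calibrated 3D fluorescence z-stacks using depth-adaptive
    intensity thresholding, removes internalized and oral-apparatus signals,
    reconstructs the anteroposterior axis and ciliary-row connectivity of
    each cell, and quantifies BB spacing, row orientation, spatial-domain
    statistics, daughter-BB calls, cell-cycle kinetics and polarity-aligned
    3D particle averages. Ships a ground-truthed synthetic cell-image
    generator so every stage of the pipeline can be validated without
    original micrographs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tiff,
    jsonlite,
    minpack.lm,
    withr,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pracma,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
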