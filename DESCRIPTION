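Package: gelbead
Title: Digital Compartment Analysis for Gelbead and Droplet Assays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Image analysis and Poisson statistics for digital
    single-cell and digital amplification assays run in hydrogel beads
    (Gelbeads) or droplets. Provides a ground-truthed synthetic scene
    generator for two-channel fluorescence micrographs of circular
    compartments, compartment segmentation with size-distribution
    statistics, Gaussian-mixture threshold fitting for positive/negative
    classification, Poisson digital quantification with confidence
    intervals and dynamic-range prediction, dilution-series efficiency
    regression, and thermal-stability comparison of compartment
    populations before and after heating.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    tiff,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: CellBasedAssays, Visualization, Classification
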