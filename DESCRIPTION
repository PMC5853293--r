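Package: ctcount
Title: Micro-CT Based Counting of Pollen Grains and Ovules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calibrated micro computed-tomography image analysis for counting
    numerous, densely aggregated high-contrast objects in plant tissue, such
    as pollen grains in orchid pollinia and ovules in ovaries. Implements
    two-point greyscale calibration (byte scaling and CT scaling against air
    and a reference liquid), the thresholding/median/Gaussian preprocessing
    chain, separation of touching objects by a descending iterative-threshold
    sweep over the component merge tree, 3D connected-component counting with
    per-object statistics, subset-to-whole volumetric extrapolation workflows
    for pollen, ovules and massulae, phantom generators with exact ground
    truth, and the downstream statistics: Euclidean-distance permutation
    ANOVA (pseudo-F) with Bonferroni post hoc tests, exact
    Mann-Whitney-Wilcoxon tests, Pagel's lambda phylogenetic signal, a
    symmetric two-state Markov model, and phylogenetic generalized least
    squares.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    tiff,
    jsonlite,
    yaml,
    ape,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    phytools,
    nlme,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
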