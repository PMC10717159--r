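Package: wormtwitch
Title: Quantification of C. elegans Muscle Contraction, Locomotion and
    Muscle Fluorescence Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying body-wall-muscle phenotypes in
    Caenorhabditis elegans from microscopy data: a contraction assay that
    converts a movie of a single worm into a per-frame body-area signal,
    applies a continuous full-body-capture quality filter, counts downward
    peaks of the mean-centred signal as contractions and reports contraction
    strength and frequency; a plate movement-trace area assay; counting of
    GFP-labelled body wall muscle nuclei and whole-body fluorescence
    intensity quantification; and the matching group-comparison statistics
    (mean +/- SEM summaries, one-way ANOVA, Tukey HSD). A synthetic-data
    module generates movies, trace images, nuclei images and per-animal
    cohort tables with exact ground truth so that every stage of the
    pipeline can be validated without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
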