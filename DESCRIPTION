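Package: bodybubbles
Title: Bubbles Reverse Correlation and Representational Similarity Analysis
    for Bodily Expression Perception
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for identifying diagnostic body parts in emotion
    categorization with the Bubbles reverse-correlation paradigm and for
    comparing candidate representational geometries against ROI voxel
    patterns. Includes octave spatial-frequency decomposition of stimuli,
    adaptive-density Bubbles sessions against simulated observers,
    classification images with random-field-theory cluster inference,
    diagnostic-proportion summaries, unbiased hit rates, repeated-measures
    ANOVA with Greenhouse-Geisser correction, candidate representational
    dissimilarity models with Kendall tau-a inference under FDR control,
    and a synthetic-data module so the whole pipeline runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
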