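Package: wormtrace
Title: Calcium-Imaging Trace Extraction and Response Classification for
    Trapped C. elegans Neuron Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable re-implementation of a calcium-imaging
    analysis pipeline for paired sensory neurons (I2, PHA) of C. elegans
    recorded in microfluidic traps: maximum-intensity Z projection,
    whole-field registration by zero-normalized cross-correlation against
    the first frame, trainable pixel segmentation (decision tree over a
    gaussian/median/range filter bank), two-object tracking by global
    distance minimization, delta-F-over-F0 normalization with
    stimulus-onset synchronization and pooling, three-level response
    classification (high/moderate/absent), static-image ROI quantification
    with background subtraction, and the accompanying statistical decision
    tree (normality-gated t/Welch/Mann-Whitney, ANOVA-Bonferroni or
    Kruskal-Wallis-Dunn) with star labels. A synthetic-scene generator with
    complete ground truth (shifts, masks, noiseless traces, response
    classes) makes every stage verifiable without raw recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    nortest,
    purrr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    zoo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
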