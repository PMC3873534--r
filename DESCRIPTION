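Package: unitsync
Title: Single-Unit Spike-Train Phenotyping and Pairwise Synchrony Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for intra-operative microwire single-unit
    recordings: firing-rate and burst-index phenotyping of sorted units,
    cross-channel duplicate-spike removal, averaged cross-correlogram
    synchrony between unit pairs with a segment-shuffle permutation null,
    and population-level statistics (Hartigan dip test of unimodality,
    Gaussian-mixture classification with AIC stopping, exact binomial and
    Fisher tests on pair counts, Pearson chi-square heterogeneity tests,
    and linear models of anesthesia covariates with FDR control). Includes
    a point-process simulator of bursty and synchronously firing
    populations that provides ground truth for every stage, and a simple
    threshold detector for synthetic wide-band voltage traces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    mclust
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
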