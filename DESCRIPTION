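Package: modifiscreen
Title: Time-Resolved Differential Genetic Interaction Mapping for
    Combinatorial RNAi Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps time-resolved, treatment-differential genetic interactions
    from combinatorial RNAi image-feature screens. Well-level phenotype tables
    are normalized (control scaling, generalized logarithm, robust Z), gated by
    assay quality control (Z'-factor, replicate correlation, plate masking,
    correlation-based feature selection), and scored for genetic interactions
    (pi-scores) by an anchored median polish with empirical-Bayes moderated
    t-tests. Per gene pair and feature, the MODIFI robust linear model
    pi = c + sigma*time + delta*treatment + error is fitted by Huber IRLS, its
    terms tested with robust F-tests, interactions classified into
    time/treatment-dependence classes, and delta-profile correlation networks
    built. A synthetic-screen simulator with known ground truth supports
    benchmarking of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    igraph,
    jsonlite
Suggests:
    MASS,
    mclust,
    yaml,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
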