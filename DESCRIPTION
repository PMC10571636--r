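Package: episig
Title: Discovery of DNA Methylation Episignatures from Infinium-Style Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Genome-wide DNA methylation episignature discovery and
    case clustering for rare-disorder cohorts profiled on Infinium-style
    beta-value arrays. Provides a seeded simulator of Infinium-like
    methylation data (bimodal probe baselines, blood cell composition
    covariates, lymphoblastoid replicates, detection failures), probe and
    sample quality filtering, age/sex/array-matched control selection,
    per-probe differential methylation with empirical-Bayes moderated
    t-statistics on M-values, signature probe selection by effect size,
    p-value rank, ROC importance and correlation pruning with a
    clustering-quality score for model selection, unsupervised projection
    of held-out samples onto a discovered profile, and a clinical
    penetrance summarizer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    limma,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
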