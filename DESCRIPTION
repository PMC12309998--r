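Package: droughtphen
Title: Drought Tolerance Indices, Response Profiling and BLUP Stability
    for Balanced Phenotype Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for balanced controlled-environment drought
    stress trials on cereal genotype panels. Computes drought
    tolerance/susceptibility indices (SI, DSI, STI, YSI, TOL) with
    threshold-based classification and consensus ranking, change
    percent-of-control response matrices with hierarchical clustering and
    tolerance-group profiles, fixed-effects ANOVA variance partitioning,
    balanced random-effects variance components with heritabilities and
    shrinkage BLUPs of genotype means, Pearson correlation networks and
    principal component summaries. Includes a seeded synthetic cohort
    generator with planted tolerance archetypes and known ground truth for
    recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    multcomp,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ape,
    lme4,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
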