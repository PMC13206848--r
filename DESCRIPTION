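Package: petsync
Title: Regional PET Quantification, Molecular Connectivity, and
    Desynchronization Scoring for Preclinical Neuroimaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for regional small-animal PET analysis in longitudinal,
    multi-arm study designs: percent injected dose (%ID) quantification,
    data-driven pseudo-reference region selection by genotype effect size,
    standardized uptake value ratios (SUVR), control-referenced z-score
    profiles, interregional (molecular) connectivity matrices with Fisher
    r-to-z transformation, bootstrap line-fit ensembles, a per-subject,
    per-region connectivity deviation score (desynchronization index) with
    first-principal-component composites, and the accompanying
    nonparametric group, coupling, and behavior statistics. Ships a
    synthetic cohort generator that emulates the statistical structure of a
    two-genotype, four-arm, three-timepoint dual-tracer study so that every
    stage of the pipeline is testable by parameter recovery.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    RNifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
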