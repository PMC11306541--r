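Package: phoskin
Title: Phosphoproteomic Subtyping and Integrative Kinase Activity Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Label-free phosphoproteomic analysis of tumor cohorts from
    MaxQuant-dialect phosphosite and evidence tables: record-level filtering
    (class-I localization, contaminants), channel-specific normalization,
    data-presence and variability filtering, resampling-based consensus
    clustering of phospho-subtypes, moderated differential statistics with
    fold-change gates, single-sample rank enrichment for gene- and
    phosphosite-level signatures, integrative inferred kinase activity (INKA)
    scoring from kinase- and substrate-centric evidence, and association of
    kinase activities with overall survival. Includes a synthetic-cohort
    generator with planted subtype structure, kinase-driven site intensities,
    intensity-dependent missingness and survival, so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    survival
Suggests:
    testthat (>= 3.0.0),
    limma,
    mclust,
    withr
Config/testthat/edition: 3
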