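Package: psblup
Title: Phenomic and Genomic Prediction for Tetraploid Breeding Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mixed-model analysis and kernel-based prediction for
    augmented row-column potato breeding trials. Provides trial
    adjustment via replicated checks, adjusted entry means and
    Piepho-Moehring broad-sense heritability from REML mixed models,
    tetraploid additive, dominance and first-degree epistatic
    relationship matrices from allele dosages, multispectral
    relationship matrices from UAV channel reflectances, GBLUP/MBLUP
    prediction under seven cross-validation scenarios, weighted
    combinations of genomic and phenomic kernels, and a synthetic-data
    generator that emulates the tetraploid multi-environment study
    design so that every stage of the pipeline is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    lme4,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
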