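Package: methylMR
Title: Bidirectional Mendelian Randomization Between DNA Methylation and Blood Lipids
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for bidirectional Mendelian randomization between CpG
    methylation and fasting blood lipids in family cohorts. Implements
    covariate-adjusted mixed-model association screening with a Bonferroni
    gate, weighted polygenic-score instruments for lipids, cross-validated
    elastic-net selection of cis-meQTL instruments for methylation,
    two-stage least-squares causal estimation in both directions with
    family random intercepts, an instrument-independence check, and the
    MR-Egger pleiotropy test. A pedigree-structured simulator generates
    genotype, methylation and phenotype data with known causal
    architecture so every stage of the pipeline can be exercised and
    validated without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    lme4,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
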