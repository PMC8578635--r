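Package: drugselect
Title: Lineage-Selective Drug Screening, Synergy, and Pharmacology Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for identifying lineage-selective compounds in large
    cancer cell line drug screens and characterizing their pharmacology.
    Implements rank-based per-drug lineage Selectivity Scores, four-parameter
    log-logistic dose-response fitting with closed-form ICx inversion and
    bootstrap confidence intervals, zero-interaction-potency (ZIP) synergy
    surfaces for checkerboard combination plates with replicate-level
    synergy/antagonism calls, genotype and expression association modelling
    (multivariate IC50 models with fold-change effects, genome-wide Spearman
    scans, regression-based mediation, ElasticNet feature selection,
    housekeeping normalization), an enzyme paralog preference estimator with
    simulation-based significance for topoisomerase decatenation assays,
    non-compartmental pharmacokinetic summaries, seeded synthetic data
    generators emulating each input, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    glmnet,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
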