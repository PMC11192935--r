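Package: crossmr
Title: Cross-Ancestry Drug-Target Mendelian Randomization with Correlated
    Instruments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for drug-target (cis) Mendelian randomization comparing two
    ancestry groups from GWAS summary statistics. Implements instrument
    selection in a gene region (MAF and F-statistic thresholds, greedy LD
    clumping), generalised least squares IVW and MR-Egger estimation under
    residual linkage disequilibrium with leverage/outlier diagnostics and
    Rucker model selection, cross-ancestry colocalization via Wakefield
    approximate Bayes factors, ancestry interaction tests with multiplicity
    control and directional-discordance classification, and a seeded
    synthetic summary-statistics generator built on an explicit structural
    model (genetic effect on a protein, protein-to-biomarker and
    biomarker-to-outcome effects, bypass pleiotropy and confounding) so every
    stage can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
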