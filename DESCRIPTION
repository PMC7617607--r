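Package: coagmr
Title: Cis-pQTL Mendelian Randomization and Colocalization for Coagulation
    Proteins and Ischemic Stroke
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for prioritizing coagulation cascade protein
    drug targets for ischemic stroke prevention from GWAS summary statistics:
    cis protein quantitative trait locus (pQTL) instrument selection with
    greedy linkage-disequilibrium clumping, allele harmonization with
    palindromic-variant exclusion, Wald-ratio and random-effects
    inverse-variance weighted Mendelian randomization (including multivariable
    MR and per-doubling venous-thromboembolism liability scaling), Bayesian
    pairwise colocalization via Wakefield approximate Bayes factors,
    summary-statistic conditional analysis and single-signal fine-mapping,
    and cross-trait reporting. A summary-statistic simulator under block
    linkage disequilibrium with known causal structure makes every stage
    testable without access to the original cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
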