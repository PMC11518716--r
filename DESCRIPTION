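Package: mrscreen
Title: Two-Sample Mendelian Randomization Screening of Metabolite Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A complete two-sample Mendelian randomization (MR) screening
    pipeline for panels of exposures (e.g. blood metabolites) against a
    binary outcome from GWAS summary statistics: instrument selection
    (association threshold, greedy LD clumping, F-statistic filter,
    annotation-based confounder exclusion), allele harmonization, five
    causal estimators (inverse-variance weighted, MR-Egger, weighted
    median, simple and weighted mode), sensitivity diagnostics (Cochran's
    Q, Egger intercept, MR-PRESSO, leave-one-out), Benjamini-Hochberg
    tiering with replication and fixed-effect meta-analysis, a simplified
    bivariate LD score regression, reverse MR, and hypergeometric pathway
    over-representation. Ships a seeded synthetic GWAS generator with
    known ground truth so the whole pipeline is testable without any
    external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse
Config/testthat/edition: 3
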