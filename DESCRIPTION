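Package: hcymr
Title: Two-Sample Mendelian Randomization of Homocysteine on Polycystic
    Ovary Syndrome
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Complete two-sample Mendelian randomization workflow for the
    causal effect of plasma homocysteine on polycystic ovary syndrome:
    GWAS summary-statistics input and allele harmonization, instrument
    selection with LD pruning and pleiotropy screening, Wald-ratio,
    inverse-variance-weighted, MR-Egger and weighted-median estimators,
    Cochran's Q heterogeneity, MR-PRESSO outlier resampling, Steiger
    directionality, leave-one-out sensitivity analysis, and fixed-effect
    meta-analysis across outcome cohorts. Ships the 14-SNP instrument
    table used by the analysis as a plain-text fixture and a synthetic
    two-sample summary-statistics generator with known ground truth for
    calibration testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    metafor,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
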