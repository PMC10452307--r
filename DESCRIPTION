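Package: cortexmr
Title: Two-Sample Mendelian Randomization of Sleep Traits on Cortical Structure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization with GWAS summary
    statistics, built around the design of a sleep-traits-to-cortical-anatomy
    study: instrument selection (genome-wide significance, minor allele
    frequency, LD clumping, confounder exclusion, F-statistic gating), allele
    harmonization with palindromic-SNP handling, five causal-effect estimators
    (Wald ratio, inverse-variance weighted, MR-Egger, weighted median, and
    mode-based), a sensitivity suite (Cochran's Q, Egger intercept,
    leave-one-out, MR-PRESSO), a 5 exposure by 68 outcome analysis grid with
    Bonferroni-tiered multiple-testing labels, and a synthetic
    summary-statistics generator with known ground truth for validating every
    stage without external data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
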