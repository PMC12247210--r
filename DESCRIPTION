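Package: mrmediate
Title: Two-Sample Mendelian Randomization with Two-Step Mediation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) mediation
    studies from GWAS summary statistics: reading, validation and allele
    harmonization of summary statistics; instrument selection by
    genome-wide significance, greedy linkage-disequilibrium clumping and
    F-statistic strength filtering; causal-effect estimation by Wald
    ratio, inverse-variance weighting, MR-Egger regression, weighted
    median and mode-based estimators; a sensitivity battery (Cochran's Q,
    Egger intercept, MR-PRESSO outlier detection, leave-one-out,
    Benjamini-Hochberg false-discovery control) with a robustness
    verdict; mediator screening cascades and two-step mediation with
    mediated-proportion calculation; and a synthetic GWAS
    summary-statistics generator with known mediation structure for
    fully reproducible, download-free validation of every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
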