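Package: leptinmr
Title: Two-Sample Mendelian Randomization of Leptin Levels and Anorexia
    Nervosa Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Complete two-sample Mendelian randomization (MR) toolkit built
    around the question of whether genetically lowered circulating leptin
    raises the risk of anorexia nervosa. Provides summary-statistic I/O and
    allele harmonization, instrument quality control (F-statistic strength
    filter, significance thresholds, LD-proxy selection), nine causal
    estimators (Wald ratio, inverse-variance weighted, MR-Egger,
    simple/weighted/penalised-weighted median, simple/weighted mode, robust
    adjusted profile score), pleiotropy and heterogeneity diagnostics
    (Cochran's Q, Egger intercept, MR-PRESSO outlier/distortion tests,
    leave-one-out, funnel/forest/scatter plot data), a binary-outcome power
    calculator, a synthetic two-sample summary-statistic generator with
    known ground truth, and bundled fixtures transcribed from published
    GWAS/EWAS instrument tables for leptin and anorexia nervosa.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
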