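Package: gebvqc
Title: Quality Assessment of Genomic Breeding Value Predictions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to assess the quality of genomic estimated breeding
    values (GEBV) from GBLUP models. Builds VanRaden method-1 genomic
    relationship matrices, estimates variance components by average
    information REML for univariate and multivariate linear mixed models
    with record-wise trait missingness, runs year-of-birth cohort
    cross-validation, and computes the LR-method bias, dispersion and
    accuracy statistics alongside traditional accuracy, the Q1Q4
    quartile-difference statistic, and ANOVA-style meta-analyses of the
    metric determinants. Includes a synthetic-data generator emulating a
    multi-herd paternal half-sib beef cattle design with known simulation
    truth for calibration testing.
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
    yaml,
    optparse
Config/testthat/edition: 3
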