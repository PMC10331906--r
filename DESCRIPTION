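Package: nestvar
Title: Intraspecific Variation in Bird Nest Morphology: Phylogenetic Signal and Comparative Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies intraspecific variation in nest morphology from
    specimen-level repeated measurements (coefficients of variation of
    log-transformed nest dimensions), estimates Pagel's lambda phylogenetic
    signal by maximum likelihood with likelihood-ratio tests, fits
    phylogenetic generalized least-squares (PGLS) regressions of trait
    variation on ecological predictors, and summarizes all statistics across
    a posterior set of phylogenies with 95% highest-density intervals. A
    synthetic-study generator produces complete specimen tables, covariates
    and tree sets with known truth for calibration and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phytools,
    withr,
    optparse
Config/testthat/edition: 3
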