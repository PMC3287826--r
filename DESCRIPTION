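Package: zipburden
Title: Gene-Based Rare-Variant Burden Testing with Zero-Inflated Poisson
    Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Collapses rare-variant carrier indicators within genes into
    per-subject counts and tests their association with binary or
    quantitative traits using zero-inflated Poisson regression with
    covariate and genotype-eigenvector adjustment. Includes genotype and
    annotation input/output, principal-component based population
    structure handling (eigenvector covariates, outlier detection,
    ancestry grouping), a replicate-based power pipeline with Bonferroni
    control, and a synthetic stratified mini-exome generator for
    end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    MASS,
    stats,
    utils,
    vcfR
Suggests:
    glmmTMB,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
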