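Package: gxenorm
Title: Genomic Reaction Norm Models for Genotype-by-Environment
    Interaction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits linear genomic reaction norm models for
    genotype-by-environment interaction in livestock body weight by
    random-regression GBLUP.  Builds a continuous environmental gradient
    from contemporary-group growth-rate BLUEs, estimates intercept and
    slope variance components by average-information REML with either
    homogeneous or gradient-dependent residual variance, derives
    environment-specific genetic variances, heritabilities and
    between-environment genetic correlations, validates them against a
    three-section multi-trait model, and performs genome-wide association
    by back-solving (scale-corrected) breeding values to SNP effects.
    Includes a synthetic-population generator with half-sib family
    structure, breed-group proportions and SNP-mediated genetic values so
    the whole pipeline can be exercised and tested without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
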