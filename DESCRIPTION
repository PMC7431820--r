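Package: twinmeth
Title: Longitudinal Biometrical Twin Models for DNA Methylation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Per-CpG bivariate ACE/ADE Cholesky twin models for DNA
    methylation M-values measured at two occasions about a decade apart,
    fitted by full-information maximum likelihood with missing occasions.
    Provides model selection between ACE and ADE variants, nested
    likelihood-ratio tests, variance decomposition and broad-sense
    heritability, cross-time etiologic correlations with Fisher-Z
    transforms, site classification (low-stability, E-dominated),
    post-fit probe filtering on implied moments, random-intercept mixed
    model comparisons of CpG sets, skew-normal regression of cross-time
    correlations, a hypergeometric set-overlap test, and a synthetic
    twin-cohort generator emulating a two-country aging-twin design for
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    lme4,
    parallel,
    stats,
    utils,
    tools,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
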