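Package: fcgrowth
Title: Latent Growth Models for Longitudinal Seed-Based Functional Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Voxelwise longitudinal modelling of seed-based resting-state
    functional connectivity. Builds Fisher-z seed-correlation maps from
    preprocessed 4D BOLD images, fits conditional latent growth curve models
    at every gray-matter voxel by full-information maximum likelihood (FIML)
    with missing data, masks results by SEM fit quality (RMSEA, CFI, SRMR),
    applies cluster-extent correction, and couples connectivity change to
    cognitive change through parallel-process growth models with delta-method
    indirect effects. Includes a synthetic-cohort generator with known ground
    truth (attrition, covariate effects, spatially clustered slope effects)
    so the full pipeline is testable end to end, plus questionnaire scoring
    and attrition-audit utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    RNifti,
    jsonlite,
    readr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    nlme,
    withr,
    patchwork
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
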