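Package: afpop
Title: Population-of-Models Analysis of Rotor Dynamics in Remodeled Human Atrial Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds experimentally calibrated populations of remodeled human
    atrial cell models by Latin hypercube sampling of ionic conductances and
    action-potential biomarker filtering, simulates functional reentry with a
    monodomain reaction-diffusion solver on 2D sheets and spherical surfaces,
    quantifies rotor dynamics (phase mapping, phase-singularity tracking,
    dominant frequency, core-meandering area, termination mechanism), applies
    in-silico ion-channel block, and links ionic conductances to reentry
    behaviour through Mann-Whitney group comparisons and partial correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    lhs,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
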