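Package: brainmediate
Title: Multilevel Whole-Brain Mediation of Cue Effects on Experienced Pleasantness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for multilevel (two-level) mediation analysis of
    cue-induced expectancy effects in task fMRI: a synthetic-data generator
    that plants known two-level mediation structure in a pseudo-randomized
    within-subject tasting design, single-trial ("beta-series") GLM
    estimation with variance-inflation-factor trial quality control,
    bootstrap inference on subject-level path coefficients including the
    covariance component of the group indirect effect, voxelwise mediation
    maps with cluster-extent thresholding and small-volume correction,
    second-level moderated mediation, finite-impulse-response time-course
    deconvolution, and the companion random-intercept mixed model for the
    behavioral ratings. Results are returned as tibbles with broom-style
    tidiers and ggplot2 visualization helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
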