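Package: gxeyield
Title: Genomic and Environmental Prediction of Maize Yield Across Environments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Multi-environment genomic prediction of maize grain yield in the
    style of the Genomes-to-Fields hybrid trials: an arc-cosine-kernel GBLUP
    with location metadata fixed effects, a debiased composite model for
    environment means (random forest + ridge + least squares), a selection
    index over a multivariate GBLUP with unstructured between-environment
    genetic covariance, and a simple two-model ensemble of the two.  Ships a
    synthetic multi-environment-trial generator with known ground truth,
    phenotype quality control and standardization, a per-environment RMSE
    evaluation harness with leaderboards, and a seeded end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
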