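Package: mbtcrsr
Title: Outcome Prediction in Disorders of Consciousness from CRS-R and
    Motor Behaviour Tool Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for acute-phase outcome prediction in disorders of
    consciousness (DOC). Implements Coma Recovery Scale-Revised (CRS-R)
    subscale scoring and diagnosis, the ten-item binary Motor Behaviour
    Tool (MBT), MBT-based progressive weighting of CRS-R subscales at the
    reflex level with a critical-increment search, nonparametric outcome
    prediction (exact and approximate Mann-Whitney U, Holm-Bonferroni
    family-wise control, sensitivity/specificity/Yule's Q for binary
    predictors), longitudinal modelling of CRS-R trajectories on an
    orthonormal polynomial basis with group mean curves, band-separation
    discrimination times and cutoff-attainment times, and a seeded
    synthetic cohort generator with logistic latent recovery for
    calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    nortest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
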