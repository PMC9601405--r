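Package: amidescreen
Title: High-Throughput Amide Coupling Screens: Design, Analytics and
    Outcome Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for stopped-flow high-throughput amide-coupling library
    screens: factorial experiment-grid design over a soft-to-harsh
    reaction-condition ramp, stopped-flow timing and reagent-usage
    accounting, outcome labelling from relative UV peak areas, library
    success-rate tables and screening heatmaps, reaction-difference
    fingerprint featurization with condition one-hot and property blocks,
    a small feed-forward neural-network outcome classifier with nested
    cross-validation, label-shuffled null baselines, temporal-set
    evaluation and classifier-score-guided experiment prioritization.
    A synthetic-campaign generator with a logistic latent response
    surface makes every pipeline stage testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    knitr,
    nnet,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
VignetteBuilder: knitr
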