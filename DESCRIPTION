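Package: rnresilience
Title: Reaction-Norm Analysis of Environmental Sensitivity from Daily Feed Intake
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the environmental sensitivity (resilience)
    of growing pigs from longitudinal daily feed intake records. Estimates a
    per-day probability that an unrecorded environmental challenge occurred,
    from the log coefficient of variation of daily feed intake via a
    two-component Gaussian mixture fitted by EM with a parametric bootstrap
    test; builds pedigree, genomic and single-step combined relationship
    matrices; fits bivariate reaction-norm animal models by restricted
    maximum likelihood on sparse mixed-model equations; and derives
    genetic-correlation trajectories of feed intake and of its slope with
    single-record production traits along the environmental gradient.
    Includes a calibrated synthetic-data generator for pedigreed, genotyped
    populations with daily intake records so the full pipeline is testable
    without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
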