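Package: occlufit
Title: Logistic Kinetics of Dentinal Tubule Occlusion
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models the time course of dentinal tubule occlusion by
    desensitizing toothpastes as Verhulst logistic growth of the percent
    occluded area towards a carrying capacity. Provides the closed-form
    logistic trajectory with equilibrium and stability analysis,
    least-squares estimation of the daily occlusion rate from summary
    time series (mean, SD, n per day) with deterministic multi-start
    bounded optimization, Welch and one-way ANOVA comparisons computed
    directly from summary statistics, a specimen-level synthetic data
    generator emulating a twice-daily brushing experiment, and
    parameter-recovery simulation for validating the estimator. Ships
    the published seven-day occlusion summaries for three pastes under
    two artificial-saliva conditions as a bundled dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    optparse,
    jsonlite
Config/testthat/edition: 3
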