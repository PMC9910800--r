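Package: horizontask
Title: Simulation and Hierarchical Bayesian Analysis of the Macaque Horizon Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyse sequential explore-exploit behaviour in
    the two-option "horizon task" with partial or complete (counterfactual)
    feedback. Provides a task generator with the study's generative statistics,
    an ideal Bayesian observer over a discretised mean grid yielding expected
    value and uncertainty per option, design builders for logistic choice models
    of first and subsequent choices (including counterfactual-update regressors
    and an information-count variant), hierarchical Bayesian logistic fitting
    via MCMC with posterior-count one-sided p-values and cell contrasts,
    behavioural summary statistics (model-defined accuracy, psychometric
    curves, repetition bias, within-horizon trends), and a parameter-recovery
    harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rjags,
    coda,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
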