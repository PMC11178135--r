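Package: igtsim
Title: Agent-Based Simulation and Fitting of the Iowa Gambling Task
Version: 0.1.0
Authors@R:
    person("Laurent", "Devel", email = "igtsim@example.org", role = c("aut", "cre"))
Description: Simulates decision-making in the Iowa Gambling Task with a
    linear-operator (delta-rule) learning agent whose subjective net gains
    weight payoffs by separate gain and loss sensitivities, and whose
    choices follow the matching law (or, optionally, Softmax). Provides the
    four-deck task environment, a parametric sweep over the memory factor
    and the two sensitivities, rejection-sampling and Nelder-Mead parameter
    recovery from block-wise preference trajectories, power-function
    learning-rate summaries with quartile subgrouping, and a synthetic
    cohort generator with known ground-truth parameters for validating the
    fitting pipeline without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
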