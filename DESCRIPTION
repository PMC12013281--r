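Package: srttddm
Title: Drift-Diffusion Modelling of Serial Response Time Task Performance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis of serial response time task (SRTT)
    experiments with an extended drift-diffusion model (DDM). Generates
    trial plans for probabilistic and mixed-deterministic sequence
    materials, simulates full synthetic cohorts whose behaviour is driven
    by DDM parameters evolving over practice, applies participant
    screening and trial filtering, computes the standard behavioural
    analyses (mixed ANOVAs with Greenhouse-Geisser correction and
    generalized eta-squared, rule-adhering error tests against chance,
    interview scoring), and estimates a hierarchical Bayesian DDM with a
    response-competition nondecision offset, Savage-Dickey Bayes factors
    for effects on model parameters, and parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    car,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
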