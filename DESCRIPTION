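Package: pathstone
Title: Direct Bayes Factor Estimation by Model-Switch Path Sampling and
    Stepping-Stone Sampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates log Bayes factors between two Bayesian phylogenetic
    models directly, by constructing a power-posterior path that connects the
    two competing models and traversing it with Markov chain Monte Carlo.
    Implements model-switch path sampling (classic and mean-of-samples
    variants), model-switch stepping-stone sampling, and harmonic mean
    baselines, together with sigmoid and flexible power-posterior schedules,
    annealing/melting (bidirectional) error diagnostics, discretization and
    sampling variance estimates, and split-interval decomposition for
    parallel or resumable runs. Ships a site-independent general
    time-reversible (GTR) model and a first-order context-dependent
    substitution model with data-augmented ancestral sequences, plus analytic
    conjugate toy models and sequence simulators for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
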