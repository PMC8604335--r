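Package: mabci
Title: Multi-Agent Bayesian Controllability Inference Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and model-based analysis of two-person
    decision-making tasks with changing controllability. Provides a
    generator for alternating self/other-controllable block schedules
    with a Rescorla-Wagner partner agent, a family of multi-agent
    Bayesian controllability inference (MABC) models with
    valence-dependent inferential biases and controllability-modulated
    value utilization, subject-level MAP estimation with
    Laplace-approximate log model evidence, random-effects Bayesian
    model selection (exceedance probabilities, Bayesian omnibus risk,
    protected exceedance probabilities), and parameter/model recovery
    experiments, all runnable on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
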