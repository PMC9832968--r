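Package: prognet
Title: Semi-Supervised Multimodal Cancer Prognosis Networks with Bayesian Variational Autoencoders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for 5-year cancer prognosis classification from gene
    expression and clinical data. Implements a semi-supervised multimodal
    classifier built around a class-conditional variational autoencoder for
    the expression modality, with variational-dropout Bayesian network
    weights, per-patient-type loss dispatch so censored and partially
    observed patients contribute to training without imputation, a learnable
    shared output layer combining per-modality votes, seed ensembles with
    logit averaging, bootstrap metric confidence intervals, Kaplan-Meier /
    log-rank stratification, connection-weights feature attribution and
    partial-dependence profiles. Includes a synthetic multimodal cohort
    generator with known ground truth (latent risk classes, censored
    exponential survival, configurable missingness) so every stage is
    testable at desk scale, plus a command-line interface for the full
    simulate-train-evaluate-attribute pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
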