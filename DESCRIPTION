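Package: dynograph
Title: Graph-Based Temporal Modeling of Longitudinal Cohort Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modeling multi-domain longitudinal panel data as a
    dynamic system. Converts long-format subject-by-visit panels into padded,
    masked sequences with lagged and change-score targets and a discrete-time
    survival coding for rare initiation events; preprocesses features with
    train-set-only median imputation, standardization, and covariate
    residualization; groups features into domain nodes, builds a
    correlation-based adjacency matrix, and propagates node states by message
    passing; fits masked recurrent sequence models (an LSTM on feature
    sequences and a graph-temporal GRU on message-passed node summaries)
    trained with Adam and validation-based early stopping; evaluates
    continuous and event outcomes with RMSE, MAE, R-squared, Pearson r,
    AUROC, average precision, and the Brier score; and summarizes latent
    system dynamics through graph-energy traces, energy-change series,
    collapse-state detection, and risk-group contrasts. A synthetic cohort
    generator with planted ground truth supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
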