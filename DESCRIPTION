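Package: symptomBN
Title: Discrete Bayesian Networks for Predicting Co-Occurring Symptoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Learns discrete Bayesian networks over dichotomized
    patient-reported symptom scores and uses them to predict the presence
    of each symptom from the others. Implements k-nearest-neighbour score
    imputation, dichotomization at the clinically relevant cut-off,
    score-based (hill-climbing, tabu search), constraint-based (PC-stable,
    grow-shrink, IAMB variants) and hybrid structure learning with AIC/BIC
    scoring, maximum-likelihood and Laplace-smoothed conditional
    probability tables, exact inference by variable elimination,
    cross-validated AUC-ROC and decile calibration, bootstrap edge-direction
    voting, and a synthetic-data generator parameterized from a published
    palliative-care symptom network so the whole pipeline is testable
    without access to the original survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    igraph,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
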