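Package: qsarpd
Title: Predictive Distributions for QSAR Property Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Represents QSAR predictions and experimental measurements as
    Gaussian probability distributions and scores them with Kullback-Leibler
    divergence. Pairs point-prediction models with applicability-domain
    error estimators (distance-to-model, local error, bagged variance,
    error models), validates them under a temporal growing-window protocol,
    and converts predictive distributions into calibrated probabilities of
    hitting single- and multi-objective target property profiles. Ships a
    synthetic-data generator that emulates temporally drifting compound
    series with heteroscedastic difficulty, replicate measurements and
    quality-control compounds, so the whole pipeline is testable without
    proprietary data.
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
    randomForest,
    e1071
Config/testthat/edition: 3
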