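Package: glucluster
Title: Cluster-Based Nocturnal Glucose Forecasting from CGM Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Short-horizon forecasting of nocturnal glucose in type 1 diabetes
    from continuous glucose monitoring (CGM) time series. Implements a
    cluster-then-forecast framework: extraction, imputation and filtering of
    6-hour nocturnal segments (72 readings at 5-minute intervals), nocturnal
    hypoglycemia labeling, hierarchical Ward clustering with silhouette-guided
    selection of the number of clusters and medoid extraction, medoid-based
    forecasters (nearest-medoid and softmax-weighted), cluster-routed and
    global tree ensembles (random forest, gradient boosting), a Holt
    double-exponential-smoothing baseline, and an RMSE/MAE/MAPE benchmark
    harness with per-step error curves. Includes a seeded synthetic
    nocturnal-CGM cohort generator with known cluster structure for offline
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    mclust,
    randomForest,
    xgboost,
    jsonlite,
    yaml,
    digest
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    ggplot2
Config/testthat/edition: 3
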