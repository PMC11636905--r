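Package: glynarx
Title: Blood Glucose Forecasting with Closed-Loop NARX Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-step blood glucose prediction from continuous glucose
    monitoring (CGM) series using a nonlinear autoregressive (NARX) neural
    network with two hidden layers. Provides CGM input/output with gap-aware
    segmentation, moving-average smoothing, open-loop (series-parallel,
    teacher-forced) training, loop closing for recursive multi-step
    forecasting at horizons of 5 to 100 minutes, the RMSE/FIT/NPE evaluation
    statistics, Clarke error-grid analysis, and a seeded synthetic CGM
    generator for fully reproducible experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
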