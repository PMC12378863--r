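Package: dosewatch
Title: Unsupervised Anomaly Detection for PET-CT Dose Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality control of PET-CT radiation dose records (body weight,
    administered PET dose, and CT dose-length product) by unsupervised anomaly
    detection. Implements Hotelling's T-squared control chart, multivariate
    statistical process control (PCA subspace T-squared and Q reconstruction
    error), a one-class support vector machine wrapper, an isolation forest,
    and the local outlier factor in novelty mode, together with a
    dual-candidate (quantile/labeling) threshold rule, imbalanced-data
    evaluation (precision, recall, F1, ROC-AUC, PR-AUC), univariate control
    limits as a baseline, and a seeded synthetic dose-record generator for
    method validation when institutional data cannot be shared.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
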