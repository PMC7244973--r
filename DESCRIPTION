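Package: mtsdx
Title: Mahalanobis-Taguchi System for Binary Diagnosis from Biomarker Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Binary diagnosis from multivariate biomarker tables with the
    Mahalanobis-Taguchi system (MTS): a Mahalanobis reference space is fitted
    from healthy subjects, refined by an individuals/moving-range control-chart
    outlier screen, and reduced to the informative variables by two-level
    orthogonal-array experiments scored with larger-the-better signal-to-noise
    ratios; the diagnostic threshold on the scaled Mahalanobis distance is set
    at the Youden-optimal point of the ROC curve. Includes Pearson-correlation
    redundancy pruning, stratified k-fold evaluation, a multivariate-normal
    generator of routine-blood-count-like two-group data, and a packaged
    worked example (a published 16-run orthogonal-array experiment over 14
    routine blood variables) reproduced exactly.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: MASS, jsonlite, stats, utils, yaml
Suggests: pROC, testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
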