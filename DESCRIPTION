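Package: handscreen
Title: Rule-Based Screening of Peripheral Nerve Injury from Hand Landmarks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects abnormal hand gestures indicating radial, ulnar, or
    median nerve injury from 21-point 3-D hand-landmark records. Computes
    clinically motivated geometric features (joint angles, webspace angles,
    thumb palmar abduction, standardized tip distance) for three screening
    gestures, selects features by ROC area under the curve, calibrates
    per-feature thresholds from training data, and classifies each gesture
    with an OR-ensemble of thresholded single-feature rules. Includes
    logistic-regression, support-vector-machine, and random-forest baselines,
    a forward-kinematic synthetic hand generator for study-shaped cohorts,
    and a full evaluation toolkit (confusion matrices, accuracy, sensitivity,
    specificity, group summaries, t-tests, subgroup analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    glmnet,
    e1071,
    randomForest,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
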