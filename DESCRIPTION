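Package: physioscreen
Title: Case-Control Screening and Classification of Multimodal Wearable
    Physiological Features
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A decision pipeline for case-control studies of multimodal
    wearable physiological features (electrodermal activity, heart rate
    variability, skin temperature) collected during cognitive stress tests.
    Provides a synthetic cohort generator with planted group effects,
    two-stage univariate screening (within-group Wilcoxon signed-rank test
    bundling and between-group Kolmogorov-Smirnov selection), an
    informative k-nearest-neighbors filter that scores and discards the
    least informative data points, robust low-variance feature filters
    (relative median absolute deviation and relative interquartile range),
    and a Monte-Carlo stratified cross-validated evaluation of PCA plus
    logistic regression, k-nearest-neighbors, random forest and support
    vector machine classifiers, including full-versus-reduced dataset
    balanced-accuracy comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    class,
    e1071,
    glmnet,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
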