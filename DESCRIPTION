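Package: ecgblend
Title: Alpha-Blended Dual-Branch Time-Frequency Classification of ECG Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Classifies single-lead ECG recordings into arrhythmia (ARR),
    congestive heart failure (CHF) and normal sinus rhythm (NSR) by fusing two
    image representations of the same segment: a continuous-wavelet-transform
    scalogram and its binarized counterpart. Convolutional feature maps are
    extracted from each image in parallel and combined by alpha blending,
    F = alpha * F_S + (1 - alpha) * F_B, before a class-weighted softmax head
    or a classical machine-learning head (SVM, random forest, KNN, XGBoost)
    performs the classification. Ships a Morse/Morlet wavelet filter bank,
    fixed-threshold and Otsu binarization, a parametric three-class synthetic
    ECG generator with the 96/30/36 class imbalance of the public PhysioNet
    cohorts, stratified splitting and 5-fold cross-validation, an experiment
    harness for ablation and blending-proportion sweeps, and feature
    diagnostics (mean activation maps, t-SNE embeddings, within-cluster sum of
    squares).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    EBImage,
    generics,
    ggplot2,
    png,
    purrr,
    randomForest,
    rlang,
    Rtsne,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost
Suggests:
    cluster,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
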