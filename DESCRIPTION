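Package: fetalpeaks
Title: Fetal R-Peak Detection from Multichannel Abdominal ECG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end framework for detecting fetal ECG R-peaks directly
    from a 12-channel maternal abdominal composite signal. Provides a synthetic
    maternal-fetal abdominal ECG simulator with ground-truth annotations, frame
    based fetal R-peak labeling (65 ms frames), a bidirectional LSTM frame
    classifier trained with class-weighted cross-entropy (implemented natively
    with batched matrix operations), detection post-processing that removes
    refractory violations and recovers missed beats, fetal heart-rate
    computation over 10-second windows with SD-ROM impulse rejection and
    adaptive smoothing, and a full evaluation toolkit (confusion metrics,
    ROC/AUC, Pearson correlation, Bland-Altman agreement, k-fold and
    leave-one-subject-out cross-validation, stratified cohort summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    zoo
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
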