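Package: eegclass
Title: Modular EEG Epoch Classification with Leakage-Aware Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A configurable framework for classifying resting-state EEG
    recordings at the epoch and subject level. Provides a synthetic
    two-class EEG cohort generator with band-limited oscillations over
    1/f noise, subject random effects and injectable ocular/muscle
    artifacts; EDF and concatenated-text readers; Butterworth bandpass
    filtering, overlapping epoch segmentation and z-scoring; tunable
    wavelet-packet artifact removal (ATAR) with aggressiveness parameter
    beta; per-channel time-domain (Hjorth parameters, moments) and
    frequency-domain (Welch band powers, spectral entropy) features;
    low-variance, mutual-information, recursive-elimination and
    minimum-redundancy-maximum-relevance feature selection; voting and
    stacking ensembles over standard classifiers with randomized
    hyperparameter search; and leakage-aware validation (random split,
    epoch-level k-fold, leave-one-subject-out) with epoch- and
    subject-level metrics, percentile bootstrap confidence intervals,
    threshold sweeps and paired fold tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    e1071,
    ranger,
    rpart,
    nnet,
    class,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
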