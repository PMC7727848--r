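Package: chanwise
Title: Channel-Wise Correlation Features and Stacked LSTM for
    Cross-Subject EEG Emotion Recognition
Version: 0.1.0
Authors@R:
    person("chanwise", "developers", email = "chanwise@example.org",
           role = c("aut", "cre"))
Description: Implements an interpretable cross-subject emotion recognition
    pipeline for multichannel EEG. Raw recordings are reduced to
    segment-mean single-channel features, from which channel-wise features
    (C x C Pearson correlation matrices between all electrode pairs) are
    computed, flattened to their strict upper triangle and fed as sequences
    to a two-layer stacked LSTM classifier trained with RMSProp.
    Includes sliding-window data augmentation, k-fold cross-validation
    (subject-mixed and subject-wise splits), an L/K/N hyperparameter sweep,
    a seeded generator of synthetic correlated EEG-like recordings with
    subject-specific base connectivity plus emotion-specific perturbations,
    correlation heatmaps, PCA embeddings of learned features, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    optparse,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
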