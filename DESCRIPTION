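Package: eegcouple
Title: Multi-Task EEG Emotion Decoding with Cross-Dimensional Coupling Constraints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint decoding of valence, arousal and dominance from windowed EEG
    segments with a hard-parameter-sharing multi-task network. A shared
    state-space (SS2D) encoder feeds three task branches; training couples the
    branches through three constraint losses: a valence-arousal circular
    (cosine) constraint on the predicted probability vector, an
    arousal-dominance energy-alignment constraint on embedding norms, and a
    valence-dominance correlation constraint on embedding cosines, combined
    with per-dimension binary cross-entropy. Includes readers for DEAP- and
    DREAMER-layout recordings, sliding-window segmentation with label
    binarization, a synthetic coupled-EEG generator with planted spectral
    signatures (left-frontal alpha asymmetry, central gamma, posterior beta),
    k-fold and leave-one-subject-out cross-validation, ablation and
    loss-weight sweep harnesses, and constraint diagnostics. The network
    forward pass and its analytic gradients are implemented in R with the
    sequential selective-scan recurrence in compiled code.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
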