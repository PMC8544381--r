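Package: notescore
Title: Clinical Note Quality Scoring with Projection Embeddings and Mixed-Model Calibration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying automatic quality scoring of clinical
    records reviewed by physicians. Provides a synthetic-data generator for
    reviewer-scored record corpora with known rater effects; positive-PMI /
    SVD word embeddings with a least-squares projection that carries a
    general-corpus embedding table into a domain (EHR-style) coordinate
    system while preserving the open-corpus vocabulary; a gated recurrent
    (LSTM) regressor mapping token sequences to a 0-10 quality score; a
    linear mixed model with REML variance components and per-cluster best
    linear unbiased predictions (BLUPs) that calibrate raw model scores for
    reviewer leniency; and evaluation utilities (mean absolute error
    reports, reviewer-by-writer heatmaps, block and quartile diagnostics)
    plus an end-to-end reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tools,
    stats,
    utils,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    MASS,
    withr,
    yaml
Config/testthat/edition: 3
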