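Package: omcdr
Title: Overlap Matrix Completion for Drug Repositioning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predicts drug-associated indications by overlap matrix
    completion on heterogeneous drug-disease (and optionally
    drug-protein-disease) networks.  Provides K-nearest-neighbour
    preprocessing for cold-start drugs and diseases, a bounded
    nuclear-norm-regularized matrix-completion solver based on the
    alternating direction method of multipliers with singular value
    thresholding, bilayer (OMC2) and tri-layer (OMC3) prediction
    pipelines that average drug-side and disease-side completions,
    cross-validation and de novo evaluation protocols with ROC, PR and
    top-k retrieval metrics, and a synthetic low-rank network generator
    for planted-recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
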