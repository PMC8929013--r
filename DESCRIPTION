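Package: pseuvote
Title: Pseudouridine Site Prediction with BPSO Feature Selection and an
    SVM Voting Ensemble
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts RNA pseudouridine (Psi) sites from U-centered sequence
    windows. Six sequence feature descriptors (one-hot, k-mer frequencies,
    k-nucleotide density, pseudo dinucleotide composition, position-specific
    k-nucleotide propensity, and nucleotide chemical properties) are each
    pruned by binary particle swarm optimization over a hybrid bit-string
    that jointly encodes a feature mask and the RBF-SVM cost/gamma pair on a
    geometric grid; the six resulting base classifiers are fused by majority
    vote. Arbitrary-length RNA is scanned with a sliding U-centered window.
    Includes stratified cross-validation, SN/SP/ACC/MCC metrics, an
    incremental-feature-selection baseline, predictor diversity correlation,
    and synthetic fixture generators with planted signal for end-to-end
    testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    e1071,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
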