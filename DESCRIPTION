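Package: marblix
Title: Binary Multimodal Monograms for Patient Case Retrieval
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Learns compact 64-bit binary patient signatures ("monograms")
    that fuse a histopathology image embedding and an immunogenomic sequence
    embedding into a single indexable code. Two cross-modal autoencoders,
    each trained to reconstruct the other modality, project the per-patient
    embeddings into aligned 128-dimensional latents; a triplet-trained
    fusion network maps the outer product of the two latents through dense
    layers to an 8x8 tanh matrix that is binarized for Hamming-distance
    case retrieval. Includes per-dimension min-max harmonization fitted on
    training folds only, patient-level stratified cross-validation, hard
    triplet mining, leave-one-out majority-vote retrieval evaluation with
    macro-averaged metrics, XOR dissimilarity maps, and a linear-Gaussian
    synthetic cohort generator (with a decoupled null mode) so the full
    pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
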