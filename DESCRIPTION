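Package: hairpinCNN
Title: Convolutional Classification of Pre-miRNA Hairpin Families with
    Open-Set Rejection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies pre-miRNA hairpin sequences into families with
    convolutional neural networks. Provides four input encodings (base-pairing
    probability matrix, ordered/unordered pair matrix, two-channel mixed
    matrix, and one-hot), a built-in McCaskill-style partition function for
    base-pairing probabilities with an import path for externally computed
    probabilities, two CNN architectures with analytic parameter counting,
    training with stratified k-fold cross-validation, open-set rejection of
    out-of-distribution sequences by thresholding the maximum softmax
    probability with ROC-based threshold selection, motif extraction from
    frequently activated convolution filters written in MEME minimal format,
    and a synthetic hairpin-family generator with shuffled, random and
    cloverleaf decoys for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
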