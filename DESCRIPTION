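Package: rnafoldnet
Title: RNA Secondary Structure Prediction with a Residual Dense
    Encoder-Decoder Network and Constrained Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts RNA secondary structure, including pseudoknots, from
    single sequences. A sequence is encoded as a 146-channel stack of binary
    contact matrices (10 unordered dinucleotide classes and 136 unordered
    tetranucleotide classes), mapped to a symmetric base-pairing score map by
    a residual dense encoder-decoder convolutional network, and decoded into
    a feasible base-pair set by relaxed primal-dual constrained optimization
    under canonical/wobble pairing, minimum hairpin separation, and
    one-partner-per-base constraints. Includes per-base evaluation metrics
    (accuracy, sensitivity, positive predictive value, F-score),
    cross-validation utilities, CT/BPSEQ/dot-bracket/FASTA input and output,
    a seeded synthetic structure generator for offline testing, and a
    training harness with a weighted cross-entropy objective.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
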