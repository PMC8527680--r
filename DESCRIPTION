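Package: pepattn
Title: Anticancer Peptide Classification with Attention-Enhanced Parallel
    CNN-LSTM Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies short peptides (5-50 residues) as anticancer or not
    from their amino-acid sequence and, optionally, per-residue secondary
    structure probability profiles produced by an external predictor.
    Implements a multi-head scaled dot-product self-attention encoder over
    one-hot sequence representations, parallel convolutional and peephole
    LSTM feature branches for sequence and structure inputs, and a dense
    sigmoid classification head, trained by backpropagation with Adam,
    dropout and early stopping. Includes FASTA and structure-profile
    readers, a stratified k-fold cross-validation harness with
    confusion-matrix metrics (accuracy, sensitivity, specificity,
    precision, Matthews correlation) and ROC/AUC, a synthetic peptide
    generator with planted compositional and structural class signal, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
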