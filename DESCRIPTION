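Package: cellattn
Title: Interpretable Additive-Attention Classification of Single-Cell RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Trains a compact additive-attention neural classifier on single-cell
    RNA-seq count matrices and uses the learned per-cell gene-attention weights for
    interpretation: global marker selection, per-cluster marker extraction,
    attention-correlation analysis, hypergeometric gene-set enrichment for
    unsupervised cluster annotation, and freeze-and-finetune transfer learning.
    Includes quality-control filtering, highly-variable-gene selection, a
    negative-binomial simulator with planted marker genes, and readers/writers for
    MatrixMarket, CSV and GMT formats.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    class,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
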