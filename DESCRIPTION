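Package: pathnn
Title: Pathway-Primed Neural Networks for Single-Cell RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Knowledge-masked feed-forward neural networks for single-cell
    RNA-seq. A sparse classifier whose first hidden layer is constrained by
    gene-set membership (one node per pathway, gene-to-node weights fixed to
    zero for non-member genes) is trained supervised on cell-type labels and
    then reused unsupervised: the last hidden layer provides a low-dimensional
    encoding for clustering, retrieval and 2-D visualisation, and the first
    hidden layer yields interpretable pathway activities. Includes repeated
    stratified holdout, leave-P-groups-out clustering validation with six
    external clustering indices, nearest-neighbour retrieval scored by mean
    average precision, hyperband hyperparameter search, hypergeometric
    gene-set enrichment with Benjamini-Hochberg correction, and a
    negative-binomial synthetic data generator with pathway-driven cell types.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
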