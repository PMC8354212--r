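Package: RFCell
Title: Gene Selection for Single-Cell RNA-Seq Clustering via Permutation and Random Forests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Supervised gene selection for single-cell RNA-seq clustering. Real
    cells are contrasted against "negative" pseudo-cells obtained by independently
    permuting each gene column of the expression matrix, a random-forest classifier
    is trained to separate the two, and genes with positive out-of-bag mean
    decrease accuracy (MDA) are selected. Also provides clustering-agreement
    statistics (normalized mutual information, Rand and adjusted Rand indices)
    implemented from their contingency-table definitions, k-means and
    Spearman-similarity hierarchical clustering, an Expr (highest mean expression)
    baseline selector, a repeat-evaluation harness, and a synthetic scRNA-seq data
    generator with known cluster labels and informative-gene mask.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    randomForest,
    Rcpp,
    stats,
    utils,
    jsonlite,
    Matrix,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
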