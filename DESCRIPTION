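Package: semimm
Title: Semi-Supervised Maximum Discriminative Local Margin Gene Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Filter feature selection for gene expression data in the
    semi-supervised setting where only a handful of samples per class carry
    labels. Implements the semiMM criterion: a signed within-class versus
    between-class k-nearest-neighbour graph margin, normalized by
    degree-weighted feature variance and blended with the normalized mutual
    information between each (discretized) gene and the class labels.
    Includes the standard comparison scores (Laplacian score, Fisher score,
    and a locality-sensitive semi-supervised margin ratio), a synthetic
    expression-data generator with known informative genes, and a benchmark
    harness reproducing the stratified-split, one-vs-rest SVM evaluation
    protocol over a grid of gene-subset sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    tidyr,
    readr,
    rlang,
    ggplot2,
    generics,
    e1071,
    pROC,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    jsonlite,
    withr
Config/testthat/edition: 3
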