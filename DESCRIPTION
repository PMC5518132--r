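Package: screenperm
Title: Permutation-Based Nonparametric Analysis of Pooled CRISPR Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Gene-level hit calling for pooled CRISPR/shRNA/siRNA screens by a
    permutation-based nonparametric test. Genes are scored by the median
    natural-log fold change of their sgRNAs' normalized read counts; a common
    null distribution is built by permuting gene labels across sgRNAs, refined
    in a second round after removing first-pass significant genes, and
    one-sided empirical p-values are adjusted by Benjamini-Hochberg. Replicates
    are combined with Fisher's method. Also provides a Dirichlet-multinomial
    screen-count simulator with ground-truth labels and a benchmarking harness
    (ROC/AUC, recall, precision, F1 at a controlled FDR).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
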