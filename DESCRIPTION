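Package: spmc
Title: Structural Perturbation Matrix Completion for Bipartite
    Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts missing links in bipartite molecular interaction
    networks (such as lncRNA-miRNA interactions) by first-order structural
    perturbation of a bilayer adjacency matrix that fuses the known
    interaction network with node similarity networks built from
    expression profiles and nucleotide sequences.  Provides the perturbed
    matrix completion predictor with degenerate-eigenvalue handling, the
    structural consistency index of link predictability, k-fold
    cross-validation with ROC/AUC and thresholded classification metrics,
    candidate ranking for case studies, and a seeded synthetic generator
    of planted low-rank interaction networks for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
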