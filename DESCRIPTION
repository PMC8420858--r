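Package: lrhunt
Title: Ligand-Receptor Interaction Discovery with Unsupervised Random Forests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers ligand-receptor interactions between two cell types
    from normalized single-cell expression matrices. The two cell types are
    linked by random-forest imputation of a block-missing interaction-space
    matrix; unsupervised multivariate random forests grown on each completed
    dataset score every candidate pair with a normalized maximal-subtree
    minimal-depth index, aggregated over multiple imputations (IMDI) and
    ranked with empirical p-values. Includes a synthetic-data generator with
    planted interactions, file readers for dense TSV and MatrixMarket input,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
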