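Package: ipad21
Title: Drug-Pathway Association Discovery by L2,1-Penalized Integrative
    Matrix Decomposition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Joint penalized decomposition of a gene-expression matrix and a
    drug-response matrix measured on the same samples into a shared
    pathway-activity matrix, pathway-membership-constrained gene loadings,
    and a row-sparse drug-pathway loading matrix (the L2,1-iPaD model).
    Row sparsity in the drug-pathway loadings is obtained with an L2,1-norm
    penalty solved by iteratively reweighted ridge regression; the
    pathway-activity matrix is estimated by accelerated projected gradient
    descent under unit-ball column constraints; missing entries are handled
    by soft-impute completion inside the alternating scheme.  The package
    provides cross-validated selection of the sparsity parameter, a
    regularization path with activation-order ranking of drug-pathway
    pairs, permutation-based empirical p-values for every pair, a seeded
    synthetic-data generator with ground truth, readers and writers for
    TSV matrices and GMT gene-set files, and a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
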