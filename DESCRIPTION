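Package: rhnmf
Title: Robust Hypergraph-Regularized Non-Negative Matrix Factorization
Version: 0.1.0
Authors@R:
    person("RHNMF", "Maintainers", email = "maintainers@rhnmf.invalid",
           role = c("aut", "cre"))
Description: Non-negative matrix factorization of gene expression matrices
    with an L2,1-norm residual loss that downweights outlier samples and a
    hypergraph Laplacian penalty that preserves high-order neighborhood
    structure among samples. The solver family covers classical NMF,
    L2,1-norm NMF, graph- and hypergraph-regularized variants via
    configuration flags. Includes k-nearest-neighbor hypergraph
    construction, sample clustering from the coefficient matrix with
    accuracy (Hungarian label matching) and normalized mutual information
    scoring, gene ranking from the basis matrix, a block-structured
    synthetic data generator with planted outliers, and a command-line
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    Matrix,
    jsonlite,
    optparse,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
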