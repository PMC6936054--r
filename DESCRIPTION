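Package: glspca
Title: Graph-Regularized Sparse PCA for Gene Expression Matrices
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Dimension reduction of gene-expression matrices by principal
    component analysis augmented with a sample-graph Laplacian term and an
    L2,1 row-sparsity penalty on the projected representation (gLSPCA).
    The model is fitted by iteratively reweighted trace minimization under
    an orthogonality constraint, solved per iteration as a dense symmetric
    eigen-problem. Includes k-nearest-neighbour affinity graph construction
    (binary or heat kernel), factor-based ranking of differentially
    expressed genes with identification-accuracy and total-relevance-score
    evaluation against a reference gene table, K-means sample clustering
    scored by best-mapping clustering accuracy, and a seeded synthetic-data
    generator with planted cluster structure and informative genes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: PrincipalComponent, DimensionReduction, Clustering,
    GeneExpression, DifferentialExpression, Software
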