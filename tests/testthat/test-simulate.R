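test_that("identical seed and parameters give bitwise-identical data", {
  a <- simulateExpression(nSamples = 30, mGenes = 50, nClusters = 3,
                          nInformative = 10, seed = 7)
  b <- simulateExpression(nSamples = 30, mGenes = 50, nClusters = 3,
                          nInformative = 10, seed = 7)
  expect_identical(SummarizedExperiment::assay(a),
                   SummarizedExperiment::assay(b))
  expect_identical(informativeGenes(a), informativeGenes(b))
  c <- simulateExpression(nSamples = 30, mGenes = 50, nClusters = 3,
                          nInformative = 10, seed = 8)
  expect_false(identical(SummarizedExperiment::assay(a),
                         SummarizedExperiment::assay(c)))
})

test_that("simulation leaves the caller's RNG state untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulateExpression(nSamples = 10, mGenes = 20,
                               nInformative = 5, seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("at zero signal informative rows are indistinguishable from noise", {
  pvals <- vapply(1:20, function(seed) {
    se <- simulateExpression(nSamples = 30, mGenes = 80, nClusters = 3,
                             nInformative = 20, signal = 0, seed = seed)
    X <- SummarizedExperiment::assay(se)
    v <- apply(X, 1, var)
    planted <- informativeGenes(se)
    wilcox.test(v[planted], v[-planted])$p.value
  }, numeric(1))
  # per-seed p-values behave as under the null: small p at the nominal rate
  # only, and no overall shift
  expect_lte(sum(pvals <= 0.01), 2L)
  expect_gt(mean(pvals), 0.2)
})

test_that("noiseless blobs equal their centroids and cluster perfectly", {
  se <- simulateExpression(nSamples = 24, mGenes = 40, nClusters = 3,
                           nInformative = 9, noiseSd = 0, seed = 2)
  X <- SummarizedExperiment::assay(se)
  lab <- trueLabels(se)
  for (cl in unique(lab)) {
    sub <- X[, lab == cl, drop = FALSE]
    expect_true(all(sub == sub[, 1]))
  }
  pred <- clusterSamples(t(X), nClusters = 3, seed = 0)
  expect_equal(accuracy(clusteringAccuracy(pred, lab)), 100)
})

test_that("labels cycle over the requested number of clusters", {
  se <- simulateExpression(nSamples = 10, mGenes = 20, nClusters = 4,
                           nInformative = 4, seed = 1)
  expect_equal(sort(unique(trueLabels(se))), 1:4)
  expect_equal(length(informativeGenes(se)), 4L)
})

test_that("curve mode produces arc-structured data with planted genes", {
  se <- simulateExpression(nSamples = 40, mGenes = 60, nClusters = 2,
                           nInformative = 10, manifold = "curve", seed = 3)
  X <- SummarizedExperiment::assay(se)
  planted <- informativeGenes(se)
  v <- apply(X, 1, var)
  # lifted arcs give planted rows much higher variance than noise rows
  expect_gt(median(v[planted]), 5 * median(v[-planted]))
})

test_that("the graph term helps on entangled arcs", {
  # geometry where local neighbourhood structure separates classes that
  # global PCA directions mix; binary kNN edges are scale-free and robust
  # to distance concentration in high dimension
  accs <- sapply(0:9, function(s) {
    se <- simulateExpression(nClusters = 2, manifold = "curve", seed = s)
    X <- SummarizedExperiment::assay(se)
    g <- knnAffinity(X, kernel = "binary")
    vapply(c(0, 0.9), function(b) {
      fit <- fitGLSPCA(X, graph = g, beta = b, gamma = 0)
      pred <- clusterSamples(fit, 2, seed = 0)
      accuracy(clusteringAccuracy(pred, trueLabels(se)))
    }, numeric(1))
  })
  expect_gte(mean(accs[2, ]), mean(accs[1, ]))
})

test_that("parameter violations are rejected", {
  expect_error(simulateExpression(nInformative = 300, mGenes = 200),
               "nInformative")
  expect_error(simulateExpression(nSamples = 5, nClusters = 6,
                                  nInformative = 2, mGenes = 10),
               "nClusters")
})
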