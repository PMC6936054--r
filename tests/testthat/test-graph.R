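test_that("binary kNN graph on collinear samples matches hand-built edges", {
  # samples at 1-D positions 0, 1, 3: NN(1) = 2, NN(2) = 1, NN(3) = 2,
  # so the OR rule keeps edges (1,2) and (2,3)
  g <- knnAffinity(lineSamples(), kNeighbors = 1, kernel = "binary")
  W <- affinityMatrix(g)
  expected <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3)
  expect_equal(unname(W), expected)
})

test_that("heat kernel weights follow exp(-d^2 / (2 sigma^2))", {
  g <- knnAffinity(lineSamples(), kNeighbors = 1, kernel = "heat",
                   sigma = 1)
  W <- affinityMatrix(g)
  expect_equal(W[1, 2], exp(-1 / 2))
  expect_equal(W[2, 3], exp(-4 / 2))
  expect_equal(W[1, 3], 0)
})

test_that("identical samples resolve ties by ascending sample index", {
  X <- matrix(0, 2, 4)
  g <- knnAffinity(X, kNeighbors = 1, kernel = "heat")
  W <- affinityMatrix(g)
  # every sample picks sample 1 (or sample 2 for sample 1); d = 0 => w = 1
  expect_true(all(W[W > 0] == 1))
  expect_equal(unname(W[, 1]), c(0, 1, 1, 1))
  expect_true(validObject(g))
})

test_that("kNeighbors outside [1, n - 1] is rejected", {
  expect_error(knnAffinity(lineSamples(), kNeighbors = 3), "kNeighbors")
  expect_error(knnAffinity(lineSamples(), kNeighbors = 0), "kNeighbors")
})

test_that("Laplacian of hand-built graphs matches the definition", {
  # path graph on 3 nodes
  Wp <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3)
  expect_equal(laplacianMatrix(laplacian(Wp)),
               matrix(c(1, -1, 0, -1, 2, -1, 0, -1, 1), 3, 3))
  # complete graph K3: diag 2, off-diagonal -1
  Wk <- matrix(1, 3, 3) - diag(3)
  expect_equal(laplacianMatrix(laplacian(Wk)), 3 * diag(3) - matrix(1, 3, 3))
})

test_that("the Laplacian annihilates the constant vector", {
  for (seed in 1:3) {
    X <- randomExpression(6, 8, seed = seed)
    L <- laplacianMatrix(laplacian(knnAffinity(X, kNeighbors = 3)))
    expect_lt(max(abs(L %*% rep(1, 8))), 1e-10)
  }
})

test_that("quadratic form identity x'Lx = 0.5 sum W_ij (x_i - x_j)^2", {
  X <- randomExpression(10, 12, seed = 7)
  g <- knnAffinity(X, kNeighbors = 4, kernel = "binary")
  W <- affinityMatrix(g)
  L <- laplacianMatrix(laplacian(g))
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(12)
    quad <- drop(t(x) %*% L %*% x)
    direct <- 0.5 * sum(W * outer(x, x, function(a, b) (a - b)^2))
    expect_lt(abs(quad - direct), 1e-9)
  }
})

test_that("zero eigenvalue multiplicity equals connected components", {
  # two disjoint edges: 4 nodes, 2 components
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 1
  W[3, 4] <- W[4, 3] <- 1
  ev <- eigen(laplacianMatrix(laplacian(W)), symmetric = TRUE,
              only.values = TRUE)$values
  expect_equal(sum(abs(ev) < 1e-10), 2L)
  expect_gt(min(ev), -1e-10)  # PSD
})

test_that("affinity graphs satisfy their structural invariants", {
  for (kern in c("binary", "heat")) {
    g <- knnAffinity(randomExpression(8, 10, seed = 2), kNeighbors = 3,
                     kernel = kern)
    W <- affinityMatrix(g)
    expect_identical(W, t(W))
    expect_true(all(diag(W) == 0))
    expect_true(all(W >= 0 & W <= 1))
    expect_true(all(rowSums(W > 0) >= 3))
    expect_true(validObject(g))
  }
})
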