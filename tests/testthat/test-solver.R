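test_that("l21Norm sums row-wise Euclidean norms", {
  expect_equal(l21Norm(diag(2)), 2)
  expect_equal(l21Norm(rbind(c(3, 4), c(0, 0))), 5)
  expect_equal(l21Norm(matrix(0, 3, 3)), 0)
})

test_that("reweighting diagonal is 1 / (2 max(row norm, floor))", {
  expect_equal(reweightDiagonal(rbind(c(3, 4))), 0.1)
  expect_equal(reweightDiagonal(rbind(c(0, 0)), epsRow = 1e-8), 5e7)
  expect_equal(reweightDiagonal(rbind(c(1, 0), c(0, 0)))[1], 0.5)
  expect_error(reweightDiagonal(diag(2), epsRow = 0), "positive")
})

test_that("objective is zero at perfect reconstruction and matches the trace expansion", {
  X <- randomExpression(5, 4, seed = 3)
  L <- matrix(0, 4, 4)
  # k = n, H square orthogonal: H H' = I so X = (XH) H'
  H <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  expect_lt(glspcaObjective(X, X %*% H, H, L, 0, 0), 1e-20)
  # any orthonormal H: ||X - XH H'||_F^2 = ||X||_F^2 - Tr(H' X'X H)
  H2 <- qr.Q(qr(matrix(rnorm(8), 4, 2)))
  expect_equal(glspcaObjective(X, X %*% H2, H2, L, 0, 0),
               sum(X^2) - sum(diag(t(H2) %*% crossprod(X) %*% H2)))
})

test_that("objective with only the sparsity term equals gamma * L2,1 norm", {
  X <- matrix(0, 3, 4)
  H <- rbind(diag(2), matrix(0, 2, 2))
  U <- X %*% H
  expect_equal(glspcaObjective(X, U, H, matrix(0, 4, 4), 0, 1), 2)
})

test_that("objective rejects incompatible shapes", {
  X <- randomExpression(5, 4)
  expect_error(glspcaObjective(X, matrix(0, 4, 2), matrix(0, 4, 2),
                               matrix(0, 4, 4), 0, 0), "incompatible")
})

test_that("beta parameterisation maps to alpha as beta/(1-beta) * etaK/etaS", {
  expect_equal(alphaFromBeta(0, 3, 2), 0)
  expect_equal(alphaFromBeta(0.5, 2, 2), 1)
  expect_error(alphaFromBeta(1, 1, 1), "beta")
})

test_that("A1 reduces to the expected limits", {
  X <- randomExpression(5, 4, seed = 5)
  L <- laplacianMatrix(laplacian(knnAffinity(X, kNeighbors = 2,
                                             kernel = "binary")))
  # beta = 1, gamma = 0: pure normalised Laplacian
  p1 <- buildA1(X, L, rep(1, 4), beta = 1, gamma = 0)
  expect_equal(p1$A1, L / p1$etaS)
  # beta = 0, gamma = 0: smallest eigenvectors of A1 = top right-singular
  # subspace of X
  p0 <- buildA1(X, L, rep(1, 4), beta = 0, gamma = 0)
  H <- smallestEigenvectors(p0$A1, 2)
  V <- svd(X)$v[, 1:2]
  expect_lt(maxPrincipalAngle(H, V), 1e-8)
})

test_that("A-form and A1-form have identical eigenvectors (sign-fixed)", {
  for (seed in 1:10) {
    set.seed(seed)
    X <- matrix(rnorm(20), 5, 4)
    L <- laplacianMatrix(laplacian(knnAffinity(X, kNeighbors = 2,
                                               kernel = "binary")))
    Dw <- if (seed == 1) rep(0.5, 4) else runif(4, 0.1, 2)
    gamma <- 0.1
    parts <- buildA1(X, L, Dw, beta = 0.3, gamma = gamma)
    al <- alphaFromBeta(0.3, parts$etaK, parts$etaS)
    A <- -crossprod(X) + al * L + gamma * diag(Dw)
    expect_lt(max(abs(smallestEigenvectors(A, 3) -
                      smallestEigenvectors(parts$A1, 3))), 1e-8)
  }
})

test_that("excessive gamma (etaK <= 0) and beta = 1 with gamma > 0 are rejected", {
  X <- randomExpression(5, 4, seed = 2)
  L <- laplacianMatrix(laplacian(knnAffinity(X, kNeighbors = 2)))
  expect_error(buildA1(X, L, rep(1, 4), beta = 0.5, gamma = 1e9),
               "lower gamma")
  expect_error(buildA1(X, L, rep(1, 4), beta = 1, gamma = 0.1),
               "beta = 1")
})

test_that("smallestEigenvectors orders, orients and validates", {
  H <- smallestEigenvectors(diag(c(3, 1, 2)), 2)
  expect_equal(abs(H), cbind(c(0, 1, 0), c(0, 0, 1)))
  expect_true(all(apply(H, 2, max) > 0))
  # k = n gives an exactly orthonormal basis
  A <- crossprod(matrix(rnorm(36), 6, 6)); A <- (A + t(A)) / 2
  V <- smallestEigenvectors(A, 6)
  expect_lt(max(abs(crossprod(V) - diag(6))), 1e-12)
  # Rayleigh quotients match the k smallest eigenvalues of a full
  # decomposition
  k <- 3
  Vk <- smallestEigenvectors(A, k)
  rq <- diag(t(Vk) %*% A %*% Vk)
  expect_equal(rq, sort(eigen(A, symmetric = TRUE,
                              only.values = TRUE)$values)[1:k],
               tolerance = 1e-10)
  expect_error(smallestEigenvectors(matrix(1:9, 3, 3), 1), "symmetric")
})

test_that("the beta = 0, gamma = 0 fit recovers classical PCA", {
  for (seed in 1:5) {
    X <- randomExpression(12, 9, seed = seed)
    fit <- fitGLSPCA(X, kNeighbors = 3, beta = 0, gamma = 0, kDims = 3)
    V <- svd(X)$v[, 1:3]
    expect_lt(maxPrincipalAngle(sampleEmbedding(fit), V), 1e-6)
  }
})

test_that("the beta = 1, gamma = 0 fit is Laplacian embedding", {
  X <- randomExpression(15, 10, seed = 4)
  gl <- laplacian(knnAffinity(X, kNeighbors = 3, kernel = "binary"))
  fit <- fitGLSPCA(X, graph = gl, beta = 1, gamma = 0)
  expect_lt(max(abs(sampleEmbedding(fit) -
                    smallestEigenvectors(laplacianMatrix(gl), 2))), 1e-8)
})

test_that("the objective decreases monotonically across settings and seeds", {
  settings <- list(c(0.1, 0.01), c(0.5, 1), c(0.9, 10))
  for (seed in 1:10) {
    se <- simulateExpression(nSamples = 30, mGenes = 50, nClusters = 3,
                             nInformative = 10, seed = seed)
    for (sg in settings) {
      fit <- fitGLSPCA(se, beta = sg[1], gamma = sg[2], tol = 1e-10,
                       maxIter = 60)
      expect_true(all(diff(objectiveTrace(fit)) <= 1e-8))
    }
  }
})

test_that("factors satisfy the orthonormality and U = XH contracts", {
  se <- simulateExpression(nSamples = 30, mGenes = 50, nClusters = 3,
                           nInformative = 10, seed = 12)
  X <- SummarizedExperiment::assay(se)
  fit <- fitGLSPCA(X, beta = 0.5, gamma = 1)
  expect_true(all(fit@orthoDevTrace < 1e-8))
  # U = XH holds bitwise, not merely to tolerance
  expect_identical(geneLoadings(fit), X %*% sampleEmbedding(fit))
})

test_that("the reweighted trace is half the L2,1 norm (surrogate identity)", {
  set.seed(21)
  for (i in 1:20) {
    H <- qr.Q(qr(matrix(rnorm(30), 10, 3)))
    Dw <- reweightDiagonal(H, epsRow = 1e-12)
    expect_lt(abs(sum(diag(t(H) %*% diag(Dw) %*% H)) - 0.5 * l21Norm(H)),
              1e-10)
  }
})

test_that("the majorisation inequality holds for random vector pairs", {
  set.seed(33)
  for (i in 1:100) {
    a <- rnorm(5); b <- rnorm(5)
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    expect_lte(na - na^2 / (2 * nb), nb - nb^2 / (2 * nb) + 1e-12)
  }
})

test_that("embedding sparsity is non-increasing in gamma", {
  se <- simulateExpression(nSamples = 40, mGenes = 80, nClusters = 3,
                           nInformative = 12, seed = 5)
  gl <- laplacian(knnAffinity(SummarizedExperiment::assay(se)))
  gammas <- c(0, 1e-2, 1e-1, 1, 10)
  l21 <- vapply(gammas, function(g)
    l21Norm(sampleEmbedding(fitGLSPCA(se, graph = gl, beta = 0.5,
                                      gamma = g))), numeric(1))
  expect_lte(cor(gammas, l21, method = "spearman"), 0)
})

test_that("invalid solver parameter combinations are rejected", {
  se <- simulateExpression(nSamples = 20, mGenes = 30, nClusters = 2,
                           nInformative = 6, seed = 1)
  expect_error(fitGLSPCA(se, beta = 1, gamma = 1), "beta = 1")
  expect_error(fitGLSPCA(se, beta = 0.5, gamma = 1e12), "lower gamma")
  expect_error(fitGLSPCA(se, kDims = 0), "kDims")
})
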