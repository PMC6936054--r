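# Core gLSPCA solver: minimise
#   ||X - U H'||_F^2 + alpha * Tr(H' L H) + gamma * ||H||_{2,1}
# subject to H'H = I, by iteratively reweighted trace minimisation. Each
# iteration replaces the L2,1 penalty by the quadratic surrogate
# gamma * Tr(H' Dw H) with Dw_ii = 1 / (2 ||h_i||_2), reducing the H update
# to the k smallest eigenvectors of a dense symmetric n x n matrix; U = XH
# is then exact. alpha is parameterised through beta in [0, 1) via
# alpha = beta / (1 - beta) * etaK / etaS, where etaK is the largest
# eigenvalue of X'X - gamma * Dw (recomputed each iteration, since Dw moves)
# and etaS the largest eigenvalue of L.

#' L2,1 norm of a matrix
#'
#' Sum over rows of the row-wise Euclidean norm:
#' \eqn{\|M\|_{2,1} = \sum_i \|m^i\|_2}. Penalising it drives whole rows to
#' zero, which is what makes the projected representation sparse by sample.
#'
#' @param M numeric matrix.
#' @return nonnegative scalar.
#' @examples
#' l21Norm(diag(2))            # 2
#' l21Norm(rbind(c(3, 4), 0))  # 5
#' @export
l21Norm <- function(M) {
  M <- as.matrix(M)
  sum(sqrt(rowSums(M^2)))
}

#' Reweighting diagonal for the L2,1 surrogate
#'
#' \eqn{D_{ii} = 1 / (2 \max(\|h_i\|_2, \epsilon))}, the diagonal that turns
#' the L2,1 penalty into a quadratic trace surrogate for the next iterate.
#' The floor \code{epsRow} guards rows that the penalty has driven to
#' (numerical) zero.
#'
#' @param H n x k matrix of the current sample embedding.
#' @param epsRow positive floor on row norms, default \code{1e-8}.
#' @return numeric n-vector of strictly positive diagonal entries.
#' @examples
#' reweightDiagonal(rbind(c(3, 4), c(0, 0)))  # 0.1 and 5e7
#' @export
reweightDiagonal <- function(H, epsRow = 1e-8) {
  if (epsRow <= 0) stop("epsRow must be positive", call. = FALSE)
  H <- as.matrix(H)
  1 / (2 * pmax(sqrt(rowSums(H^2)), epsRow))
}

#' Penalised reconstruction objective
#'
#' The exact (non-surrogate) objective
#' \eqn{\|X - U H^T\|_F^2 + \alpha\,\mathrm{Tr}(H^T L H) + \gamma \|H\|_{2,1}}.
#'
#' @param X genes x samples matrix.
#' @param U m x k gene loadings.
#' @param H n x k sample embedding.
#' @param L n x n graph Laplacian matrix.
#' @param alpha nonnegative graph-term weight.
#' @param gamma nonnegative sparsity weight.
#' @return scalar objective value.
#' @export
glspcaObjective <- function(X, U, H, L, alpha, gamma) {
  X <- as.matrix(X); U <- as.matrix(U); H <- as.matrix(H); L <- as.matrix(L)
  if (nrow(U) != nrow(X) || nrow(H) != ncol(X) || ncol(U) != ncol(H) ||
      nrow(L) != ncol(X) || ncol(L) != ncol(X)) {
    stop("incompatible shapes: X is ", nrow(X), "x", ncol(X),
         ", U is ", nrow(U), "x", ncol(U), ", H is ", nrow(H), "x", ncol(H),
         ", L is ", nrow(L), "x", ncol(L), call. = FALSE)
  }
  R <- X - U %*% t(H)
  sum(R^2) + alpha * sum(H * (L %*% H)) + gamma * l21Norm(H)
}

#' Graph-term weight implied by the beta parameterisation
#'
#' \eqn{\alpha = \frac{\beta}{1-\beta} \cdot \frac{\eta_k}{\eta_s}}, which
#' maps the unbounded graph weight alpha onto beta in [0, 1). beta = 1 is
#' the pure Laplacian-embedding limit and is handled as a special case, not
#' through this map.
#'
#' @param beta graph/data trade-off in [0, 1).
#' @param etaK largest eigenvalue of \eqn{X^T X - \gamma D_w}, > 0.
#' @param etaS largest eigenvalue of the graph Laplacian, > 0.
#' @return nonnegative scalar alpha.
#' @export
alphaFromBeta <- function(beta, etaK, etaS) {
  if (beta < 0 || beta >= 1) {
    stop("beta must lie in [0, 1); beta = 1 is the pure Laplacian-embedding",
         " limit and has no finite alpha", call. = FALSE)
  }
  if (etaK <= 0 || etaS <= 0) {
    stop("etaK and etaS must be positive", call. = FALSE)
  }
  beta / (1 - beta) * etaK / etaS
}

# Core of buildA1 working from a precomputed X'X (n x n). When etaK/etaS
# are supplied they are reused instead of recomputed, so the solver can fix
# the normalisation (and hence alpha) across iterations.
.buildA1core <- function(XtX, L, reweight, beta, gamma,
                         etaK = NULL, etaS = NULL) {
  n <- nrow(XtX)
  if (beta == 1 && gamma > 0) {
    stop("beta = 1 with gamma > 0 is not allowed: at beta = 1 the ",
         "sparsity term drops out of the eigen-problem; set gamma = 0",
         call. = FALSE)
  }
  M <- XtX - gamma * diag(reweight, nrow = n)
  if (is.null(etaK)) {
    etaK <- max(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
  }
  if (etaK <= 0) {
    stop("largest eigenvalue of X'X - gamma * Dw is not positive ",
         "(etaK = ", format(etaK), "); lower gamma", call. = FALSE)
  }
  if (is.null(etaS)) {
    etaS <- max(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  }
  if (etaS <= 0) {
    stop("graph Laplacian has no positive eigenvalue (empty graph?)",
         call. = FALSE)
  }
  A1 <- (1 - beta) * (diag(n) - M / etaK) + beta * L / etaS
  A1 <- (A1 + t(A1)) / 2
  list(A1 = A1, etaK = etaK, etaS = etaS)
}

#' Normalised trace-minimisation matrix for the H update
#'
#' Builds \eqn{A_1 = (1-\beta)\,(I - (X^T X - \gamma D_w)/\eta_k) +
#' \beta L / \eta_s}, whose k smallest eigenvectors give the updated sample
#' embedding. The sign of the \eqn{\gamma D_w} term follows the expansion of
#' the objective (\eqn{A = -X^T X + \alpha L + \gamma D_w}) and the
#' definition of \eqn{\eta_k} as the largest eigenvalue of
#' \eqn{X^T X - \gamma D_w}; eigenvectors of \eqn{A_1} and \eqn{A} coincide.
#'
#' @param X genes x samples matrix.
#' @param L n x n graph Laplacian matrix.
#' @param reweight numeric n-vector, the reweighting diagonal \eqn{D_w}.
#' @param beta graph/data trade-off in [0, 1]; beta = 1 requires gamma = 0.
#' @param gamma nonnegative sparsity weight.
#' @return list with elements \code{A1} (symmetric n x n), \code{etaK},
#'   \code{etaS}.
#' @export
buildA1 <- function(X, L, reweight, beta, gamma) {
  X <- as.matrix(X)
  L <- if (methods::is(L, "GraphLaplacian")) L@L else as.matrix(L)
  n <- ncol(X)
  if (nrow(L) != n || length(reweight) != n) {
    stop("L and reweight must match the number of samples (", n, ")",
         call. = FALSE)
  }
  if (beta < 0 || beta > 1) stop("beta must lie in [0, 1]", call. = FALSE)
  if (gamma < 0) stop("gamma must be nonnegative", call. = FALSE)
  .buildA1core(crossprod(X), L, reweight, beta, gamma)
}

#' Eigenvectors of the k smallest eigenvalues of a symmetric matrix
#'
#' Columns are ordered by ascending eigenvalue; each column's sign is fixed
#' so that its largest-magnitude entry is positive (reproducibility).
#'
#' @param A symmetric matrix (asymmetry beyond 1e-10 is an error).
#' @param k number of eigenvectors, in [1, n].
#' @return n x k matrix with orthonormal columns.
#' @export
smallestEigenvectors <- function(A, k) {
  A <- as.matrix(A)
  n <- nrow(A)
  if (ncol(A) != n) stop("A must be square", call. = FALSE)
  if (max(abs(A - t(A))) > 1e-10) {
    stop("A must be symmetric (within 1e-10)", call. = FALSE)
  }
  k <- as.integer(k)
  if (k < 1L || k > n) stop("k must lie in [1, n]", call. = FALSE)
  A <- (A + t(A)) / 2
  e <- eigen(A, symmetric = TRUE)
  # eigen() returns eigenvalues in descending order; take the tail, reversed
  idx <- rev(seq(n - k + 1L, n))
  V <- e$vectors[, idx, drop = FALSE]
  .fixSigns(V)
}

# Flip each column so its largest-magnitude entry is positive; first such
# entry wins on exact magnitude ties.
.fixSigns <- function(V) {
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

#' Fit graph-regularized sparse PCA
#'
#' Iteratively reweighted trace minimisation of the penalised reconstruction
#' objective under the orthogonality constraint \eqn{H^T H = I}. Each
#' iteration: build the normalised trace matrix \code{A1} from the current
#' reweighting diagonal, take the \code{kDims} smallest eigenvectors as
#' \code{H}, set \eqn{U = XH}, re-evaluate the true objective and update
#' the reweighting diagonal. The normalising eigenvalues \eqn{\eta_k},
#' \eqn{\eta_s} -- and with them the implied graph weight alpha -- are fixed
#' at the initialisation \eqn{D_w = I}, so every iteration majorises and
#' minimises the same objective and descent is monotone. Stops when the
#' relative objective change drops below \code{tol} or after
#' \code{maxIter} iterations.
#'
#' Limits: \code{beta = 0, gamma = 0} recovers classical PCA (span of H =
#' top-k right singular subspace of X); \code{beta = 1, gamma = 0} is
#' Laplacian embedding (H = smallest-eigenvalue eigenvectors of L); for
#' beta = 1 the recorded objective is the embedding criterion
#' \eqn{\mathrm{Tr}(H^T L H)} since alpha is not finite there.
#'
#' @param x genes x samples matrix or \code{SummarizedExperiment}.
#' @param graph an \linkS4class{AffinityGraph}, a
#'   \linkS4class{GraphLaplacian}, or \code{NULL} to build the default
#'   heat-kernel kNN graph (\code{kNeighbors}, \code{sigma}) from \code{x}.
#' @param kDims number of components k (default 2).
#' @param beta graph/data trade-off in [0, 1] (default 0.5); beta = 1
#'   requires \code{gamma = 0}.
#' @param gamma nonnegative L2,1 sparsity weight (default 1).
#' @param kNeighbors,kernel,sigma graph construction parameters used when
#'   \code{graph} is \code{NULL} (defaults: 5, heat, 1).
#' @param maxIter maximum iterations (default 100).
#' @param tol relative objective-change tolerance (default 1e-6).
#' @param epsRow floor on row norms in the reweighting diagonal
#'   (default 1e-8).
#' @return a \linkS4class{GLSPCAFit}.
#' @examples
#' se <- simulateExpression(nSamples = 30, mGenes = 60, nClusters = 3,
#'                          nInformative = 9, seed = 1)
#' fit <- fitGLSPCA(se, beta = 0.5, gamma = 1)
#' fit
#' @export
fitGLSPCA <- function(x, graph = NULL, kDims = 2L, beta = 0.5, gamma = 1,
                      kNeighbors = 5L, kernel = c("heat", "binary"),
                      sigma = 1, maxIter = 100L, tol = 1e-6,
                      epsRow = 1e-8) {
  kernel <- match.arg(kernel)
  X <- .asExpressionMatrix(x)
  m <- nrow(X); n <- ncol(X)
  kDims <- as.integer(kDims)
  if (kDims < 1L || kDims > min(m, n)) {
    stop("kDims must lie in [1, min(m, n)]", call. = FALSE)
  }
  if (beta < 0 || beta > 1) stop("beta must lie in [0, 1]", call. = FALSE)
  if (gamma < 0) stop("gamma must be nonnegative", call. = FALSE)
  if (beta == 1 && gamma > 0) {
    stop("beta = 1 with gamma > 0 is not allowed: at beta = 1 the ",
         "sparsity term drops out of the eigen-problem; set gamma = 0",
         call. = FALSE)
  }
  if (tol <= 0 || maxIter < 1L) {
    stop("tol must be positive and maxIter at least 1", call. = FALSE)
  }

  if (is.null(graph)) {
    graph <- knnAffinity(X, kNeighbors = kNeighbors, kernel = kernel,
                         sigma = sigma)
  }
  gl <- if (methods::is(graph, "GraphLaplacian")) graph else laplacian(graph)
  L <- gl@L
  if (nrow(L) != n) {
    stop("graph was built over ", nrow(L), " samples but X has ", n,
         call. = FALSE)
  }

  XtX <- crossprod(X)
  Dw <- rep(1, n)          # Algorithm initialisation: Dw = I
  obj <- numeric(0)
  orthoDev <- numeric(0)
  alpha <- NA_real_
  etaK <- etaS <- NA_real_
  converged <- FALSE
  H <- NULL

  for (it in seq_len(maxIter)) {
    # etaK, etaS (and with them alpha) are fixed at the initialisation
    # Dw = I: this makes every later iteration an exact majorise-minimise
    # step on one fixed objective, which is what guarantees monotone
    # descent; letting etaK track Dw would let the objective itself drift
    parts <- .buildA1core(XtX, L, Dw, beta, gamma,
                          etaK = if (it > 1L) etaK else NULL,
                          etaS = if (it > 1L) etaS else NULL)
    etaK <- parts$etaK; etaS <- parts$etaS
    # at beta = 1 the data and sparsity terms vanish and A1 = L / etaS;
    # diagonalise L itself so the embedding is the Laplacian eigenbasis
    # even when the smallest eigenvalues are (near-)degenerate
    H <- if (beta == 1) smallestEigenvectors(L, kDims)
         else smallestEigenvectors(parts$A1, kDims)
    U <- X %*% H
    if (beta < 1) {
      alpha <- alphaFromBeta(beta, etaK, etaS)
      f <- glspcaObjective(X, U, H, L, alpha, gamma)
    } else {
      alpha <- NA_real_
      f <- sum(H * (L %*% H))   # Laplacian-embedding criterion
    }
    if (!is.finite(f)) {
      stop("objective became non-finite at iteration ", it, call. = FALSE)
    }
    obj <- c(obj, f)
    orthoDev <- c(orthoDev,
                  max(abs(crossprod(H) - diag(ncol(H)))))
    Dw <- reweightDiagonal(H, epsRow)
    if (it >= 2L &&
        abs(obj[it - 1L] - obj[it]) / max(1, abs(obj[it - 1L])) < tol) {
      converged <- TRUE
      break
    }
  }

  rownames(U) <- rownames(X)
  rownames(H) <- colnames(X)
  colnames(U) <- colnames(H) <- paste0("PC", seq_len(kDims))

  methods::new("GLSPCAFit",
    U = U, H = H, reweight = Dw, objectiveTrace = obj,
    orthoDevTrace = orthoDev,
    nIter = length(obj), converged = converged, alpha = alpha,
    etaK = etaK, etaS = etaS,
    params = list(kDims = kDims, beta = beta, gamma = gamma,
                  maxIter = as.integer(maxIter), tol = tol,
                  epsRow = epsRow,
                  kNeighbors = if (methods::is(graph, "AffinityGraph"))
                    graph@kNeighbors else NA_integer_,
                  kernel = if (methods::is(graph, "AffinityGraph"))
                    graph@kernel else NA_character_,
                  sigma = if (methods::is(graph, "AffinityGraph"))
                    graph@sigma else NA_real_)
  )
}

#' @rdname GLSPCAFit-class
#' @aliases sampleEmbedding,GLSPCAFit-method
#' @param x a \code{GLSPCAFit}
#' @export
setMethod("sampleEmbedding", "GLSPCAFit", function(x) x@H)

#' @rdname GLSPCAFit-class
#' @aliases geneLoadings,GLSPCAFit-method
#' @export
setMethod("geneLoadings", "GLSPCAFit", function(x) x@U)

#' @rdname GLSPCAFit-class
#' @aliases objectiveTrace,GLSPCAFit-method
#' @export
setMethod("objectiveTrace", "GLSPCAFit", function(x) x@objectiveTrace)

#' @rdname GLSPCAFit-class
#' @aliases nIterations,GLSPCAFit-method
#' @export
setMethod("nIterations", "GLSPCAFit", function(x) x@nIter)

#' @rdname GLSPCAFit-class
#' @aliases fitParams,GLSPCAFit-method
#' @export
setMethod("fitParams", "GLSPCAFit", function(x) x@params)

setMethod("show", "GLSPCAFit", function(object) {
  p <- object@params
  cat("GLSPCAFit:", nrow(object@U), "genes x", nrow(object@H),
      "samples,", ncol(object@H), "components\n")
  cat(sprintf("  beta = %g, gamma = %g, alpha = %s\n", p$beta, p$gamma,
              if (is.na(object@alpha)) "NA (Laplacian embedding)"
              else sprintf("%.6g", object@alpha)))
  cat(sprintf("  %d iteration(s), %s (tol = %g)\n", object@nIter,
              if (object@converged) "converged" else "not converged",
              p$tol))
  cat(sprintf("  objective: %.6g -> %.6g\n",
              object@objectiveTrace[1L],
              object@objectiveTrace[object@nIter]))
  cat(sprintf("  ||H||_{2,1} = %.6g\n", l21Norm(object@H)))
})
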