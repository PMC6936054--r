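#' @import methods
NULL

#' Sample-sample k-nearest-neighbour affinity graph
#'
#' Symmetric nonnegative affinity matrix over samples, built by
#' \code{\link{knnAffinity}}. Neighbourhoods are symmetrised with the OR rule:
#' an edge is kept when either endpoint lists the other among its k nearest
#' neighbours. Weights are binary (0/1) or heat-kernel
#' \eqn{\exp(-d^2 / 2\sigma^2)}.
#'
#' @slot W symmetric nonnegative n x n affinity matrix, zero diagonal,
#'   entries in [0, 1], dimnames = sample ids.
#' @slot kNeighbors number of nearest neighbours requested per sample.
#' @slot kernel \code{"binary"} or \code{"heat"}.
#' @slot sigma heat-kernel bandwidth (ignored for the binary kernel).
#'
#' @seealso \code{\link{knnAffinity}}, \code{\link{laplacian}}
#' @export
setClass("AffinityGraph",
  representation(
    W = "matrix",
    kNeighbors = "integer",
    kernel = "character",
    sigma = "numeric"
  )
)

setValidity("AffinityGraph", function(object) {
  W <- object@W
  msg <- character(0)
  if (nrow(W) != ncol(W)) {
    msg <- c(msg, "affinity matrix must be square")
  }
  if (max(abs(W - t(W))) > 0) {
    msg <- c(msg, "affinity matrix must be exactly symmetric")
  }
  if (any(diag(W) != 0)) {
    msg <- c(msg, "affinity matrix must have a zero diagonal")
  }
  if (any(W < 0) || any(W > 1)) {
    msg <- c(msg, "affinity weights must lie in [0, 1]")
  }
  if (!object@kernel %in% c("binary", "heat")) {
    msg <- c(msg, "kernel must be 'binary' or 'heat'")
  }
  deg <- rowSums(W > 0)
  if (any(deg < object@kNeighbors)) {
    msg <- c(msg, sprintf(
      "every sample must keep >= %d positive-weight neighbours after OR symmetrisation",
      object@kNeighbors
    ))
  }
  if (length(msg)) msg else TRUE
})

#' Unnormalised graph Laplacian of a sample affinity graph
#'
#' \eqn{L = \mathrm{Deg} - W} for a symmetric nonnegative affinity matrix
#' \eqn{W}, where \eqn{\mathrm{Deg}} is the diagonal matrix of row sums of
#' \eqn{W}. \eqn{L} is symmetric positive semi-definite and annihilates the
#' constant vector.
#'
#' @slot L symmetric n x n Laplacian matrix.
#' @slot degree numeric n-vector of node degrees \eqn{d_i = \sum_j W_{ij}}.
#'
#' @seealso \code{\link{laplacian}}
#' @export
setClass("GraphLaplacian",
  representation(
    L = "matrix",
    degree = "numeric"
  )
)

setValidity("GraphLaplacian", function(object) {
  L <- object@L
  msg <- character(0)
  if (nrow(L) != ncol(L)) {
    msg <- c(msg, "Laplacian must be square")
  }
  if (max(abs(L - t(L))) > 1e-12) {
    msg <- c(msg, "Laplacian must be symmetric")
  }
  if (max(abs(rowSums(L))) > 1e-8) {
    msg <- c(msg, "Laplacian rows must sum to zero")
  }
  if (length(object@degree) != nrow(L)) {
    msg <- c(msg, "degree vector length must match the Laplacian dimension")
  }
  if (length(msg)) msg else TRUE
})

#' Fitted graph-regularized sparse PCA model
#'
#' Result of \code{\link{fitGLSPCA}}: the gene-side factor \eqn{U = XH}, the
#' sample embedding \eqn{H} with orthonormal columns, the L2,1 reweighting
#' diagonal at convergence and the per-iteration objective trace.
#'
#' @slot U m x k gene loading matrix, \eqn{U = XH}, rownames = gene ids.
#' @slot H n x k sample embedding with orthonormal columns,
#'   rownames = sample ids.
#' @slot reweight n-vector of reweighting diagonal entries
#'   \eqn{1 / (2 \max(\|h_i\|_2, \epsilon))} at the last iterate.
#' @slot objectiveTrace per-iteration value of the penalised reconstruction
#'   objective (see \code{\link{glspcaObjective}}).
#' @slot orthoDevTrace per-iteration max-norm deviation of \eqn{H^T H}
#'   from the identity.
#' @slot nIter number of iterations performed.
#' @slot converged whether the relative-change stopping rule fired before
#'   \code{maxIter}.
#' @slot alpha graph-term weight implied by beta (\code{NA} in the pure
#'   Laplacian-embedding limit beta = 1).
#' @slot etaK largest eigenvalue of \eqn{X^T X - \gamma D_w} at the
#'   initialisation \eqn{D_w = I}; fixed across iterations.
#' @slot etaS largest eigenvalue of the graph Laplacian.
#' @slot params list of fitting parameters (kDims, beta, gamma, tol,
#'   maxIter, epsRow, graph settings).
#'
#' @seealso \code{\link{fitGLSPCA}}
#' @export
setClass("GLSPCAFit",
  representation(
    U = "matrix",
    H = "matrix",
    reweight = "numeric",
    objectiveTrace = "numeric",
    orthoDevTrace = "numeric",
    nIter = "integer",
    converged = "logical",
    alpha = "numeric",
    etaK = "numeric",
    etaS = "numeric",
    params = "list"
  )
)

setValidity("GLSPCAFit", function(object) {
  msg <- character(0)
  k <- ncol(object@H)
  if (ncol(object@U) != k) {
    msg <- c(msg, "U and H must have the same number of columns")
  }
  if (length(object@reweight) != nrow(object@H)) {
    msg <- c(msg, "reweight length must equal the number of samples")
  }
  gram <- crossprod(object@H)
  if (max(abs(gram - diag(k))) > 1e-8) {
    msg <- c(msg, "columns of H must be orthonormal")
  }
  if (length(msg)) msg else TRUE
})

#' Per-gene ranking derived from the gene-side factor
#'
#' Scores for all genes, the permutation sorting them in descending order
#' (ties broken by ascending gene index) and the size of the selected
#' top set.
#'
#' @slot scores numeric m-vector of nonnegative per-gene scores.
#' @slot order integer permutation of gene indices, descending score.
#' @slot topN number of genes in the selected set.
#' @slot geneIds character m-vector of gene identifiers.
#'
#' @seealso \code{\link{rankGenes}}, \code{\link{selectTopGenes}}
#' @export
setClass("GeneRanking",
  representation(
    scores = "numeric",
    order = "integer",
    topN = "integer",
    geneIds = "character"
  )
)

setValidity("GeneRanking", function(object) {
  msg <- character(0)
  m <- length(object@scores)
  if (m == 0L) {
    msg <- c(msg, "ranking must contain at least one gene")
  }
  if (length(object@geneIds) != m) {
    msg <- c(msg, "geneIds length must match scores")
  }
  if (length(object@order) != m || !setequal(object@order, seq_len(m))) {
    msg <- c(msg, "order must be a permutation of gene indices")
  }
  if (any(!is.finite(object@scores))) {
    msg <- c(msg, "scores must be finite")
  }
  if (object@topN < 1L || object@topN > m) {
    msg <- c(msg, "topN must lie in [1, number of genes]")
  }
  if (m > 1L && any(diff(object@scores[object@order]) > 0)) {
    msg <- c(msg, "order must sort scores in descending order")
  }
  if (length(msg)) msg else TRUE
})

#' Clustering evaluation by best-mapping accuracy
#'
#' Predicted and true sample labels together with the label bijection that
#' maximises agreement, the resulting accuracy (percent) and the confusion
#' matrix.
#'
#' @slot predicted integer vector of predicted cluster labels (1-based
#'   internal encoding).
#' @slot truth integer vector of true class labels (1-based internal
#'   encoding).
#' @slot mapping data.frame with columns \code{predicted} and \code{truth}
#'   giving the optimal label bijection (padded when class counts differ).
#' @slot acc best-mapping accuracy in percent.
#' @slot confusion confusion matrix, rows = predicted, columns = truth.
#'
#' @seealso \code{\link{clusteringAccuracy}}
#' @export
setClass("ClusterEvaluation",
  representation(
    predicted = "integer",
    truth = "integer",
    mapping = "data.frame",
    acc = "numeric",
    confusion = "matrix"
  )
)

setValidity("ClusterEvaluation", function(object) {
  msg <- character(0)
  if (length(object@predicted) != length(object@truth)) {
    msg <- c(msg, "predicted and truth must have equal length")
  }
  if (object@acc < 0 || object@acc > 100) {
    msg <- c(msg, "accuracy must lie in [0, 100]")
  }
  if (length(msg)) msg else TRUE
})
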