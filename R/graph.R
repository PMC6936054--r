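# kNN affinity graph over samples and its unnormalised Laplacian.
# Neighbourhoods use Euclidean distance between sample columns and are
# symmetrised with the OR rule before kernel weighting.

#' Build the k-nearest-neighbour affinity graph over samples
#'
#' Computes Euclidean distances between sample columns, keeps the
#' \code{kNeighbors} nearest neighbours of every sample (self excluded, ties
#' broken by ascending sample index), symmetrises with the OR rule and
#' weights the retained edges either 0/1 (\code{"binary"}) or with the heat
#' kernel \eqn{\exp(-d^2 / 2\sigma^2)} (\code{"heat"}, the default used
#' throughout: k = 5 neighbours, sigma = 1).
#'
#' @param x genes x samples matrix or \code{SummarizedExperiment}.
#' @param kNeighbors number of nearest neighbours, in [1, n - 1].
#' @param kernel edge weighting, \code{"heat"} (default) or \code{"binary"}.
#' @param sigma heat-kernel bandwidth, > 0.
#' @return an \linkS4class{AffinityGraph}.
#' @examples
#' se <- simulateExpression(nSamples = 12, mGenes = 30, nClusters = 2,
#'                          nInformative = 6, seed = 1)
#' g <- knnAffinity(se, kNeighbors = 3)
#' range(affinityMatrix(g))
#' @export
knnAffinity <- function(x, kNeighbors = 5L, kernel = c("heat", "binary"),
                        sigma = 1) {
  kernel <- match.arg(kernel)
  mat <- .asExpressionMatrix(x)
  n <- ncol(mat)
  kNeighbors <- as.integer(kNeighbors)
  if (kNeighbors < 1L || kNeighbors >= n) {
    stop("kNeighbors must lie in [1, n - 1]; got ", kNeighbors,
         " for n = ", n, call. = FALSE)
  }
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)

  d <- as.matrix(stats::dist(t(mat)))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    di <- d[i, ]
    di[i] <- Inf
    # order() is stable: equidistant neighbours resolve by ascending index
    nb <- order(di)[seq_len(kNeighbors)]
    adj[i, nb] <- TRUE
  }
  adj <- adj | t(adj)

  W <- matrix(0, n, n)
  if (kernel == "binary") {
    W[adj] <- 1
  } else {
    w <- exp(-d[adj]^2 / (2 * sigma^2))
    # keep retained edges strictly positive even when the kernel underflows
    W[adj] <- pmax(w, .Machine$double.xmin)
  }
  diag(W) <- 0
  dimnames(W) <- list(colnames(mat), colnames(mat))

  methods::new("AffinityGraph", W = W, kNeighbors = kNeighbors,
               kernel = kernel, sigma = as.numeric(sigma))
}

#' Graph Laplacian of an affinity graph
#'
#' \eqn{L = \mathrm{Deg} - W} with \eqn{\mathrm{Deg}} the diagonal degree
#' matrix \eqn{d_i = \sum_j W_{ij}}. The result is symmetric, positive
#' semi-definite, and has the constant vector in its null space.
#'
#' @param graph an \linkS4class{AffinityGraph}, or a symmetric nonnegative
#'   affinity matrix.
#' @return a \linkS4class{GraphLaplacian}.
#' @examples
#' W <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3)  # path graph
#' laplacianMatrix(laplacian(W))
#' @export
laplacian <- function(graph) {
  W <- if (methods::is(graph, "AffinityGraph")) graph@W else graph
  if (!is.matrix(W) || nrow(W) != ncol(W)) {
    stop("expected an AffinityGraph or a square affinity matrix",
         call. = FALSE)
  }
  deg <- rowSums(W)
  L <- diag(deg, nrow = length(deg)) - W
  dimnames(L) <- dimnames(W)
  methods::new("GraphLaplacian", L = L, degree = deg)
}

#' @rdname AffinityGraph-class
#' @aliases affinityMatrix,AffinityGraph-method
#' @param x an \code{AffinityGraph}
#' @export
setMethod("affinityMatrix", "AffinityGraph", function(x) x@W)

#' @rdname GraphLaplacian-class
#' @aliases laplacianMatrix,GraphLaplacian-method
#' @param x a \code{GraphLaplacian}
#' @export
setMethod("laplacianMatrix", "GraphLaplacian", function(x) x@L)

#' @rdname GraphLaplacian-class
#' @aliases degreeVector,GraphLaplacian-method
#' @export
setMethod("degreeVector", "GraphLaplacian", function(x) x@degree)

setMethod("show", "AffinityGraph", function(object) {
  cat("AffinityGraph over", nrow(object@W), "samples\n")
  cat("  kernel:", object@kernel,
      if (object@kernel == "heat") sprintf("(sigma = %g)", object@sigma)
      else "", "\n")
  cat("  kNeighbors:", object@kNeighbors, "\n")
  cat("  edges (undirected):", sum(object@W > 0) / 2, "\n")
})

setMethod("show", "GraphLaplacian", function(object) {
  cat("GraphLaplacian over", nrow(object@L), "samples\n")
  cat("  degree range: [", sprintf("%.4g", min(object@degree)), ", ",
      sprintf("%.4g", max(object@degree)), "]\n", sep = "")
})
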