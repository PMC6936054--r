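# Parameter-grid evaluation over (beta, gamma): fit, cluster, score by
# best-mapping accuracy against supplied true labels.

#' Grid search over the graph and sparsity weights
#'
#' Fits the model for every (beta, gamma) pair, clusters the sample
#' embedding with K-means (number of clusters = number of distinct true
#' labels) and reports the best-mapping clustering accuracy, the L2,1 norm
#' of the embedding and the iteration count. Pairs with beta = 1 and
#' gamma > 0 are marked invalid and skipped rather than aborting the grid.
#'
#' @param x genes x samples matrix or \code{SummarizedExperiment}.
#' @param truth true class labels, one per sample; required, since the grid
#'   is selected by clustering accuracy.
#' @param betaGrid numeric vector of beta values in [0, 1].
#' @param gammaGrid numeric vector of nonnegative gamma values.
#' @param kDims number of components (default 2).
#' @param graph optional prebuilt \linkS4class{AffinityGraph} or
#'   \linkS4class{GraphLaplacian}; built once with defaults when
#'   \code{NULL}.
#' @param seed K-means seed (default 0).
#' @param ... further arguments passed to \code{\link{fitGLSPCA}}.
#' @return data.frame with one row per pair: \code{beta}, \code{gamma},
#'   \code{valid}, \code{acc}, \code{l21}, \code{iterations}, \code{best}
#'   (logical flag on the highest-accuracy valid row).
#' @export
gridSearch <- function(x, truth, betaGrid, gammaGrid, kDims = 2L,
                       graph = NULL, seed = 0L, ...) {
  if (length(betaGrid) == 0L || length(gammaGrid) == 0L) {
    stop("betaGrid and gammaGrid must be nonempty", call. = FALSE)
  }
  mat <- .asExpressionMatrix(x)
  if (length(truth) != ncol(mat)) {
    stop("truth must have one label per sample", call. = FALSE)
  }
  if (is.null(graph)) graph <- knnAffinity(mat)
  nClusters <- length(unique(truth))

  cells <- expand.grid(beta = betaGrid, gamma = gammaGrid,
                       KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    beta <- cells$beta[i]; gamma <- cells$gamma[i]
    if (beta == 1 && gamma > 0) {
      return(data.frame(beta = beta, gamma = gamma, valid = FALSE,
                        acc = NA_real_, l21 = NA_real_,
                        iterations = NA_integer_))
    }
    fit <- tryCatch(
      fitGLSPCA(mat, graph = graph, kDims = kDims, beta = beta,
                gamma = gamma, ...),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      return(data.frame(beta = beta, gamma = gamma, valid = FALSE,
                        acc = NA_real_, l21 = NA_real_,
                        iterations = NA_integer_))
    }
    pred <- clusterSamples(fit, nClusters = nClusters, seed = seed)
    ev <- clusteringAccuracy(pred, truth)
    data.frame(beta = beta, gamma = gamma, valid = TRUE,
               acc = accuracy(ev), l21 = l21Norm(sampleEmbedding(fit)),
               iterations = nIterations(fit))
  })
  out <- do.call(rbind, res)
  out$best <- FALSE
  if (any(out$valid)) {
    out$best[which(out$valid)[which.max(out$acc[out$valid])]] <- TRUE
  }
  out
}
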