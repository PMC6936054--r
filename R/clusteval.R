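# K-means clustering of the sample embedding and the best-mapping
# clustering accuracy (ACC): predicted labels are matched to true labels by
# the bijection maximising agreement, solved exactly as a maximum-weight
# bipartite matching on the (zero-padded) confusion matrix.

#' Cluster samples in the learned embedding
#'
#' Runs K-means on the rows of the sample embedding with multiple random
#' restarts under a fixed seed; the caller's RNG state is restored
#' afterwards.
#'
#' @param H n x k embedding matrix or a \linkS4class{GLSPCAFit}.
#' @param nClusters number of clusters, in [2, n].
#' @param seed RNG seed for reproducibility (default 0).
#' @param restarts number of random restarts (default 50).
#' @return integer n-vector of cluster labels in 1..nClusters.
#' @export
clusterSamples <- function(H, nClusters, seed = 0L, restarts = 50L) {
  if (methods::is(H, "GLSPCAFit")) H <- sampleEmbedding(H)
  H <- as.matrix(H)
  n <- nrow(H)
  nClusters <- as.integer(nClusters)
  if (nClusters < 2L || nClusters > n) {
    stop("nClusters must lie in [2, n]; got ", nClusters, " for n = ", n,
         call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  # centers = n is the trivial optimum (one sample per cluster) but is
  # rejected by stats::kmeans, so handle it directly
  if (nClusters == n) return(seq_len(n))
  set.seed(seed)
  km <- suppressWarnings(
    stats::kmeans(H, centers = nClusters, nstart = restarts, iter.max = 100L)
  )
  as.integer(km$cluster)
}

# Exact maximum-agreement bijection between the row and column labels of a
# confusion matrix, via maximum-weight bipartite matching on the square
# zero-padded table. Weights are shifted by +1 so that zero-count pairs
# remain eligible edges and the matching is perfect.
.bestAssignment <- function(tab) {
  k <- max(nrow(tab), ncol(tab))
  T2 <- matrix(0, k, k)
  T2[seq_len(nrow(tab)), seq_len(ncol(tab))] <- tab
  el <- which(T2 >= 0, arr.ind = TRUE)
  g <- igraph::make_bipartite_graph(
    c(rep(FALSE, k), rep(TRUE, k)),
    edges = as.vector(t(cbind(el[, 1L], el[, 2L] + k)))
  )
  m <- igraph::max_bipartite_match(g, weights = T2[el] + 1)$matching
  assign <- m[seq_len(k)] - k
  list(assignment = assign,
       matched = sum(T2[cbind(seq_len(k), assign)]))
}

#' Best-mapping clustering accuracy
#'
#' \eqn{ACC = \frac{1}{n}\sum_i \delta(p_i, \mathrm{map}(q_i)) \times 100},
#' where \eqn{\mathrm{map}} is the bijection between predicted and true
#' labels that maximises the number of agreements (exact assignment optimum
#' on the confusion matrix, padded square when class counts differ).
#'
#' @param predicted vector of predicted cluster labels (any atomic type).
#' @param truth vector of true class labels, same length.
#' @return a \linkS4class{ClusterEvaluation}.
#' @examples
#' accuracy(clusteringAccuracy(c(2, 2, 1, 1), c(1, 1, 2, 2)))  # 100
#' accuracy(clusteringAccuracy(c(1, 2, 2, 2), c(1, 1, 2, 2)))  # 75
#' @export
clusteringAccuracy <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop("predicted and truth must have equal length", call. = FALSE)
  }
  n <- length(truth)
  if (n < 1L) stop("labels must be nonempty", call. = FALSE)
  pf <- factor(predicted)
  tf <- factor(truth)
  tab <- table(pf, tf)
  res <- .bestAssignment(tab)
  acc <- 100 * res$matched / n

  pLev <- levels(pf); tLev <- levels(tf)
  k <- length(res$assignment)
  mapping <- data.frame(
    predicted = c(pLev, rep(NA_character_, k - length(pLev))),
    truth = ifelse(res$assignment <= length(tLev),
                   tLev[pmin(res$assignment, length(tLev))],
                   NA_character_),
    stringsAsFactors = FALSE
  )
  methods::new("ClusterEvaluation",
    predicted = as.integer(pf), truth = as.integer(tf),
    mapping = mapping, acc = acc,
    confusion = unclass(tab)
  )
}

#' @rdname ClusterEvaluation-class
#' @aliases accuracy,ClusterEvaluation-method
#' @param x a \code{ClusterEvaluation}
#' @export
setMethod("accuracy", "ClusterEvaluation", function(x) x@acc)

#' @rdname ClusterEvaluation-class
#' @aliases bestMapping,ClusterEvaluation-method
#' @export
setMethod("bestMapping", "ClusterEvaluation", function(x) x@mapping)

#' @rdname ClusterEvaluation-class
#' @aliases confusionMatrix,ClusterEvaluation-method
#' @export
setMethod("confusionMatrix", "ClusterEvaluation", function(x) x@confusion)

setMethod("show", "ClusterEvaluation", function(object) {
  cat("ClusterEvaluation over", length(object@truth), "samples\n")
  cat(sprintf("  ACC = %.2f%%\n", object@acc))
  ok <- !is.na(object@mapping$predicted) & !is.na(object@mapping$truth)
  cat("  mapping:",
      paste(sprintf("%s->%s", object@mapping$predicted[ok],
                    object@mapping$truth[ok]), collapse = ", "), "\n")
})
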