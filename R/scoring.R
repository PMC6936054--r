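# Gene ranking from the gene-side factor U = XH and its evaluation against
# a reference gene table (identification accuracy, total relevance score).

#' Per-gene scores from the gene-side factor
#'
#' Aggregates each gene's row of loadings across components: \code{"l1"}
#' (default) sums absolute loadings, \code{"l2"} takes the row Euclidean
#' norm. Genes that load strongly on the retained components score high and
#' are the candidates for differential expression under this
#' factorisation-based (not test-based) definition.
#'
#' @param U m x k loading matrix or a \linkS4class{GLSPCAFit}.
#' @param mode \code{"l1"} or \code{"l2"}.
#' @return named nonnegative m-vector of scores.
#' @examples
#' geneScores(rbind(a = c(3, -4), b = c(0, 0)))        # a = 7, b = 0
#' geneScores(rbind(a = c(3, -4), b = c(0, 0)), "l2")  # a = 5, b = 0
#' @export
geneScores <- function(U, mode = c("l1", "l2")) {
  mode <- match.arg(mode)
  if (methods::is(U, "GLSPCAFit")) U <- geneLoadings(U)
  U <- as.matrix(U)
  if (nrow(U) == 0L || ncol(U) == 0L) {
    stop("cannot score genes from an empty loading matrix", call. = FALSE)
  }
  s <- switch(mode,
    l1 = rowSums(abs(U)),
    l2 = sqrt(rowSums(U^2))
  )
  names(s) <- rownames(U)
  s
}

#' Select the top-scoring genes
#'
#' Orders genes by descending score, ties broken by ascending gene index,
#' and marks the first \code{n} as the selected set.
#'
#' @param scores numeric m-vector of gene scores.
#' @param n size of the selected set, in [1, m].
#' @param geneIds gene identifiers; defaults to \code{names(scores)} or
#'   \code{gene_1 ...} when unnamed.
#' @return a \linkS4class{GeneRanking}.
#' @export
selectTopGenes <- function(scores, n, geneIds = NULL) {
  m <- length(scores)
  if (m == 0L) stop("scores must be nonempty", call. = FALSE)
  n <- as.integer(n)
  if (n < 1L || n > m) {
    stop("n must lie in [1, ", m, "]; got ", n, call. = FALSE)
  }
  if (is.null(geneIds)) geneIds <- names(scores)
  if (is.null(geneIds)) geneIds <- paste0("gene_", seq_len(m))
  if (length(geneIds) != m) {
    stop("geneIds length must match scores", call. = FALSE)
  }
  ord <- order(-scores, seq_len(m), method = "radix")
  methods::new("GeneRanking", scores = as.numeric(scores),
               order = as.integer(ord), topN = n,
               geneIds = as.character(geneIds))
}

#' Rank genes from a fitted model
#'
#' Convenience wrapper: scores genes from the gene-side factor and selects
#' the top set (default 100, capped at the number of genes).
#'
#' @param fit a \linkS4class{GLSPCAFit}.
#' @param mode score aggregation, \code{"l1"} (default) or \code{"l2"}.
#' @param topN size of the selected set, capped at m (default 100).
#' @return a \linkS4class{GeneRanking}.
#' @export
rankGenes <- function(fit, mode = c("l1", "l2"), topN = 100L) {
  s <- geneScores(fit, mode = match.arg(mode))
  selectTopGenes(s, n = min(as.integer(topN), length(s)))
}

#' @rdname GeneRanking-class
#' @aliases topGenes,GeneRanking-method
#' @param x a \code{GeneRanking}
#' @param n number of genes (defaults to the stored topN)
#' @export
setMethod("topGenes", "GeneRanking", function(x, n = NULL) {
  if (is.null(n)) n <- x@topN
  n <- as.integer(n)
  if (n < 1L || n > length(x@scores)) {
    stop("n must lie in [1, ", length(x@scores), "]", call. = FALSE)
  }
  idx <- x@order[seq_len(n)]
  data.frame(rank = seq_len(n), gene_id = x@geneIds[idx],
             score = x@scores[idx], row.names = NULL,
             stringsAsFactors = FALSE)
})

setMethod("show", "GeneRanking", function(object) {
  cat("GeneRanking over", length(object@scores), "genes; top",
      object@topN, "selected\n")
  top <- topGenes(object, n = min(5L, object@topN))
  cat("  leading genes:",
      paste(sprintf("%s (%.4g)", top$gene_id, top$score), collapse = ", "),
      "\n")
})

# Selected gene ids of a ranking (its top-N set).
.selectedGenes <- function(ranking) {
  stopifnot(methods::is(ranking, "GeneRanking"))
  ranking@geneIds[ranking@order[seq_len(ranking@topN)]]
}

#' Identification accuracy of a gene selection
#'
#' Percentage of the selected genes that appear in the reference gene
#' table: \eqn{IA = |selected \cap reference| / |selected| \times 100}.
#'
#' @param ranking a \linkS4class{GeneRanking}; its top-N set is evaluated.
#' @param reference named numeric vector (names = reference gene ids), as
#'   returned by \code{\link{readReferenceTable}}, or a character vector of
#'   gene ids.
#' @return percentage in [0, 100].
#' @export
identificationAccuracy <- function(ranking, reference) {
  sel <- .selectedGenes(ranking)
  refIds <- if (is.character(reference)) reference else names(reference)
  if (is.null(refIds)) {
    stop("reference must be a character vector of gene ids or a named ",
         "numeric vector", call. = FALSE)
  }
  100 * mean(sel %in% refIds)
}

#' Total relevance score of a gene selection
#'
#' Sum of reference relevance scores over the selected genes; genes absent
#' from the reference table contribute 0.
#'
#' @inheritParams identificationAccuracy
#' @param reference named numeric vector of relevance scores.
#' @return nonnegative scalar.
#' @export
totalRelevanceScore <- function(ranking, reference) {
  if (!is.numeric(reference) || is.null(names(reference))) {
    stop("reference must be a named numeric vector of relevance scores",
         call. = FALSE)
  }
  sel <- .selectedGenes(ranking)
  sum(reference[intersect(sel, names(reference))])
}
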