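# Seeded synthetic expression matrices with planted cluster structure and
# informative genes. Two geometries: "blobs" (cluster-specific mean shifts
# on the informative genes, Gaussian noise everywhere) and "curve"
# (samples along interleaved arcs in a 2-D latent space, lifted into the
# informative genes by a random loading matrix - a geometry where the
# sample-graph term is informative and plain PCA is not).

#' Simulate a gene-expression matrix with planted structure
#'
#' Generates an m x n expression matrix with \code{nClusters} sample
#' groups. In \code{"blobs"} mode each informative gene is assigned one
#' cluster and its mean is shifted by \code{signal} in that cluster's
#' samples; all other entries are N(0, noiseSd^2) noise. In \code{"curve"}
#' mode samples lie along \code{nClusters} interleaved arcs in a 2-D latent
#' space, lifted into the informative gene rows by a random loading matrix
#' with entries N(0, signal^2), plus noise; cluster identity is the arc.
#'
#' Identical \code{seed} and parameters give bitwise-identical output; the
#' caller's RNG state is left untouched.
#'
#' @param nSamples number of samples n (default 60).
#' @param mGenes number of genes m (default 200).
#' @param nClusters number of sample clusters (default 3).
#' @param nInformative number of planted informative genes (default 20).
#' @param signal mean-shift magnitude (blobs) or loading scale (curve),
#'   default 4.
#' @param noiseSd additive Gaussian noise standard deviation (default 1).
#' @param manifold \code{"blobs"} (default) or \code{"curve"}.
#' @param seed RNG seed (default 0).
#' @return a \code{SummarizedExperiment} with assay \code{"expression"}
#'   (genes x samples), \code{colData(x)$cluster} true labels,
#'   \code{rowData(x)$informative} logical flags and the generator
#'   parameters in \code{metadata(x)$params}.
#' @examples
#' se <- simulateExpression(nSamples = 30, mGenes = 50, nClusters = 3,
#'                          nInformative = 10, seed = 7)
#' table(SummarizedExperiment::colData(se)$cluster)
#' @export
simulateExpression <- function(nSamples = 60L, mGenes = 200L,
                               nClusters = 3L, nInformative = 20L,
                               signal = 4, noiseSd = 1,
                               manifold = c("blobs", "curve"),
                               seed = 0L) {
  manifold <- match.arg(manifold)
  nSamples <- as.integer(nSamples); mGenes <- as.integer(mGenes)
  nClusters <- as.integer(nClusters)
  nInformative <- as.integer(nInformative)
  if (nInformative > mGenes) {
    stop("nInformative must not exceed mGenes", call. = FALSE)
  }
  if (nClusters > nSamples || nClusters < 1L) {
    stop("nClusters must lie in [1, nSamples]", call. = FALSE)
  }
  if (noiseSd < 0 || signal < 0) {
    stop("signal and noiseSd must be nonnegative", call. = FALSE)
  }

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)

  labels <- rep_len(seq_len(nClusters), nSamples)
  informative <- sort(sample.int(mGenes, nInformative))

  M <- matrix(0, mGenes, nSamples)
  if (manifold == "blobs") {
    # marker-gene design: informative gene j is upregulated by `signal`
    # in one cluster, cycling over clusters
    geneCluster <- rep_len(seq_len(nClusters), nInformative)
    for (j in seq_len(nInformative)) {
      M[informative[j], labels == geneCluster[j]] <- signal
    }
  } else {
    tArc <- stats::runif(nSamples, 0, pi)
    # interleaved half-moon pairs: odd arcs open downwards, even arcs are
    # shifted and flipped so consecutive arcs entangle
    u <- ifelse(labels %% 2L == 1L, cos(tArc), 1 - cos(tArc)) +
      2 * ((labels - 1L) %/% 2L)
    v <- ifelse(labels %% 2L == 1L, sin(tArc), 0.5 - sin(tArc))
    latent <- cbind(u, v)
    A <- matrix(stats::rnorm(nInformative * 2L, sd = signal),
                nInformative, 2L)
    M[informative, ] <- A %*% t(latent)
  }
  X <- M + matrix(stats::rnorm(mGenes * nSamples, sd = noiseSd),
                  mGenes, nSamples)
  dimnames(X) <- list(paste0("gene_", seq_len(mGenes)),
                      paste0("sample_", seq_len(nSamples)))

  params <- list(nSamples = nSamples, mGenes = mGenes,
                 nClusters = nClusters, nInformative = nInformative,
                 signal = signal, noiseSd = noiseSd, manifold = manifold,
                 seed = as.integer(seed))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(expression = X),
    colData = S4Vectors::DataFrame(
      cluster = labels, row.names = colnames(X)),
    rowData = S4Vectors::DataFrame(
      informative = seq_len(mGenes) %in% informative,
      row.names = rownames(X)),
    metadata = list(params = params)
  )
}

#' True cluster labels of a simulated dataset
#'
#' @param x a \code{SummarizedExperiment} from
#'   \code{\link{simulateExpression}}.
#' @return integer label vector.
#' @export
trueLabels <- function(x) {
  SummarizedExperiment::colData(x)$cluster
}

#' Indices of the planted informative genes
#'
#' @param x a \code{SummarizedExperiment} from
#'   \code{\link{simulateExpression}}.
#' @return integer vector of gene indices.
#' @export
informativeGenes <- function(x) {
  which(SummarizedExperiment::rowData(x)$informative)
}
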