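#' @describeIn AffinityGraph affinity matrix W
#' @param x an object of the documented class
#' @export
setGeneric("affinityMatrix", function(x) standardGeneric("affinityMatrix"))

#' @describeIn GraphLaplacian Laplacian matrix L
#' @export
setGeneric("laplacianMatrix", function(x) standardGeneric("laplacianMatrix"))

#' @describeIn GraphLaplacian node degree vector
#' @export
setGeneric("degreeVector", function(x) standardGeneric("degreeVector"))

#' @describeIn GLSPCAFit sample embedding H (n x k, orthonormal columns)
#' @export
setGeneric("sampleEmbedding", function(x) standardGeneric("sampleEmbedding"))

#' @describeIn GLSPCAFit gene loading matrix U = XH
#' @export
setGeneric("geneLoadings", function(x) standardGeneric("geneLoadings"))

#' @describeIn GLSPCAFit per-iteration objective values
#' @export
setGeneric("objectiveTrace", function(x) standardGeneric("objectiveTrace"))

#' @describeIn GLSPCAFit number of iterations performed
#' @export
setGeneric("nIterations", function(x) standardGeneric("nIterations"))

#' @describeIn GLSPCAFit fitting parameters as a list
#' @export
setGeneric("fitParams", function(x) standardGeneric("fitParams"))

#' @describeIn GeneRanking top-N genes as a data.frame (rank, gene_id, score)
#' @param n number of genes to return (defaults to the stored topN)
#' @export
setGeneric("topGenes", function(x, n = NULL) standardGeneric("topGenes"))

#' @describeIn ClusterEvaluation best-mapping accuracy in percent
#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))

#' @describeIn ClusterEvaluation optimal predicted-to-truth label mapping
#' @export
setGeneric("bestMapping", function(x) standardGeneric("bestMapping"))

#' @describeIn ClusterEvaluation confusion matrix (rows = predicted)
#' @export
setGeneric("confusionMatrix", function(x) standardGeneric("confusionMatrix"))
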