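# Delimited-text I/O for expression matrices, labels, reference gene tables
# and gene rankings. Delimiter is auto-detected from the header line (tab vs
# comma) when not given; numbers are written with "%.17g" so that values
# round-trip through text exactly.

.detectDelimiter <- function(path) {
  header <- readLines(path, n = 1L)
  nTab <- lengths(regmatches(header, gregexpr("\t", header, fixed = TRUE)))
  nComma <- lengths(regmatches(header, gregexpr(",", header, fixed = TRUE)))
  # single-column files have no delimiter in the header; default to tab and
  # let the column-count checks produce the informative error
  if (nTab >= nComma) "\t" else ","
}

.checkIds <- function(ids, what, path) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicated ", what, " id(s) in '", path, "': ",
         paste(utils::head(dup, 5L), collapse = ", "), call. = FALSE)
  }
  invisible(ids)
}

.validateExpressionMatrix <- function(mat, source = "expression matrix") {
  if (nrow(mat) < 2L || ncol(mat) < 2L) {
    stop(source, " must have at least 2 genes and 2 samples", call. = FALSE)
  }
  bad <- which(!is.finite(mat), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(source, " contains missing or non-finite values, e.g. gene '",
         rownames(mat)[bad[1L, 1L]], "', sample '",
         colnames(mat)[bad[1L, 2L]], "'", call. = FALSE)
  }
  invisible(mat)
}

#' Read a gene-expression matrix from delimited text
#'
#' Reads a TSV/CSV matrix with one id column and a header row and returns a
#' \linkS4class{SummarizedExperiment} whose single assay \code{"expression"}
#' is oriented genes x samples regardless of the file orientation.
#'
#' @param path path to the delimited file. The first column holds row ids
#'   and the header row holds column ids.
#' @param delimiter field delimiter; \code{NULL} (default) auto-detects tab
#'   vs comma from the header line.
#' @param genesOnRows if \code{TRUE} (default) file rows are genes and
#'   columns are samples; if \code{FALSE} the file is transposed on read so
#'   the returned object is still genes x samples.
#' @return a \code{SummarizedExperiment} with assay \code{"expression"}.
#' @details Fails with an informative error on malformed numeric cells
#'   (naming the offending row and column), duplicated ids, missing values
#'   and matrices smaller than 2 x 2.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' se0 <- simulateExpression(nSamples = 6, mGenes = 10, nClusters = 2,
#'                           nInformative = 3, seed = 1)
#' writeExpression(se0, tf)
#' dim(readExpression(tf))
#' @export
readExpression <- function(path, delimiter = NULL, genesOnRows = TRUE) {
  if (!file.exists(path)) stop("file not found: '", path, "'", call. = FALSE)
  if (is.null(delimiter)) delimiter <- .detectDelimiter(path)
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "\"", comment.char = "")
  if (ncol(df) < 2L) {
    stop("matrix file '", path, "' needs an id column plus at least one ",
         "data column", call. = FALSE)
  }
  rowIds <- as.character(df[[1L]])
  colIds <- colnames(df)[-1L]
  .checkIds(rowIds, if (genesOnRows) "gene" else "sample", path)
  .checkIds(colIds, if (genesOnRows) "sample" else "gene", path)
  body <- df[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    col <- body[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      badRow <- which(is.na(num) & !toupper(trimws(col)) %in% c("NA", "NAN"))
      if (length(badRow)) {
        stop("malformed numeric cell in '", path, "' at row '",
             rowIds[badRow[1L]], "', column '", colIds[j], "': '",
             col[badRow[1L]], "'", call. = FALSE)
      }
      body[[j]] <- num
    }
  }
  mat <- as.matrix(body)
  dimnames(mat) <- list(rowIds, colIds)
  if (!genesOnRows) mat <- t(mat)
  .validateExpressionMatrix(mat, paste0("matrix in '", path, "'"))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(expression = mat)
  )
}

#' Write a gene-expression matrix to delimited text
#'
#' Writes genes x samples with a header row of sample ids and a leading
#' \code{gene_id} column, at full double precision.
#'
#' @param x a \code{SummarizedExperiment} or a numeric matrix with dimnames.
#' @param path output path.
#' @param delimiter field delimiter, default tab.
#' @return invisibly, the path.
#' @export
writeExpression <- function(x, path, delimiter = "\t") {
  mat <- .asExpressionMatrix(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(mat)), collapse = delimiter), con)
  body <- apply(mat, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = delimiter))
  writeLines(paste(rownames(mat), body, sep = delimiter), con)
  invisible(path)
}

# Accepts SummarizedExperiment or plain matrix; returns genes x samples
# matrix with dimnames filled in.
.asExpressionMatrix <- function(x) {
  if (methods::is(x, "SummarizedExperiment")) {
    x <- SummarizedExperiment::assay(x)
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("expected a numeric matrix or a SummarizedExperiment", call. = FALSE)
  }
  if (is.null(rownames(x))) rownames(x) <- paste0("gene_", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("sample_", seq_len(ncol(x)))
  x
}

#' Read sample labels from a two-column delimited file
#'
#' @param path path to a headered two-column file (sample id, class label).
#' @param delimiter field delimiter; auto-detected when \code{NULL}.
#' @return data.frame with columns \code{sample_id}, \code{label} (original
#'   string) and \code{class} (integer codes 0, 1, ... in order of first
#'   appearance), row order preserved.
#' @export
readLabels <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("file not found: '", path, "'", call. = FALSE)
  if (is.null(delimiter)) delimiter <- .detectDelimiter(path)
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "\"", comment.char = "")
  if (ncol(df) < 2L) {
    stop("label file '", path, "' must have two columns ",
         "(sample id, label)", call. = FALSE)
  }
  sampleId <- as.character(df[[1L]])
  label <- as.character(df[[2L]])
  .checkIds(sampleId, "sample", path)
  data.frame(
    sample_id = sampleId,
    label = label,
    class = as.integer(factor(label, levels = unique(label))) - 1L,
    stringsAsFactors = FALSE
  )
}

#' Align a label table to the samples of an expression matrix
#'
#' @param labels data.frame from \code{\link{readLabels}}.
#' @param x expression matrix or \code{SummarizedExperiment} whose column
#'   names are sample ids.
#' @return integer class vector ordered as the columns of \code{x}.
#' @export
alignLabels <- function(labels, x) {
  mat <- .asExpressionMatrix(x)
  idx <- match(colnames(mat), labels$sample_id)
  if (anyNA(idx)) {
    missing <- colnames(mat)[is.na(idx)][1L]
    stop("sample '", missing, "' has no entry in the label table",
         call. = FALSE)
  }
  labels$class[idx]
}

#' Read a reference gene table (gene id, relevance score)
#'
#' Reference tables list known disease-relevant genes with a nonnegative
#' relevance score; they back the identification-accuracy and
#' total-relevance-score metrics.
#'
#' @param path path to a headered two-column file.
#' @param delimiter field delimiter; auto-detected when \code{NULL}.
#' @return named numeric vector of scores, names = gene ids.
#' @export
readReferenceTable <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("file not found: '", path, "'", call. = FALSE)
  if (is.null(delimiter)) delimiter <- .detectDelimiter(path)
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "\"", comment.char = "")
  if (ncol(df) < 2L) {
    stop("reference table '", path, "' must have two columns ",
         "(gene id, score)", call. = FALSE)
  }
  ids <- as.character(df[[1L]])
  .checkIds(ids, "gene", path)
  scores <- suppressWarnings(as.numeric(df[[2L]]))
  if (anyNA(scores)) {
    stop("non-numeric relevance score for gene '",
         ids[which(is.na(scores))[1L]], "' in '", path, "'", call. = FALSE)
  }
  if (any(scores < 0)) {
    stop("relevance scores must be nonnegative in '", path, "'",
         call. = FALSE)
  }
  stats::setNames(scores, ids)
}

#' Write a gene ranking to TSV
#'
#' Writes the top-N selection of a \linkS4class{GeneRanking} as a TSV with
#' columns \code{rank}, \code{gene_id}, \code{score}, descending score,
#' at full double precision.
#'
#' @param ranking a \linkS4class{GeneRanking}.
#' @param path output path.
#' @param all write the full ranking instead of the top-N selection.
#' @return invisibly, the path.
#' @export
writeGeneRanking <- function(ranking, path, all = FALSE) {
  stopifnot(methods::is(ranking, "GeneRanking"))
  tab <- topGenes(ranking, n = if (all) length(ranking@scores) else NULL)
  if (nrow(tab) == 0L) stop("refusing to write an empty ranking",
                            call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("rank\tgene_id\tscore", con)
  writeLines(sprintf("%d\t%s\t%.17g", tab$rank, tab$gene_id, tab$score), con)
  invisible(path)
}

#' Read back a gene ranking written by \code{\link{writeGeneRanking}}
#'
#' @param path path to the ranking TSV.
#' @return data.frame with columns \code{rank}, \code{gene_id},
#'   \code{score}.
#' @export
readGeneRanking <- function(path) {
  if (!file.exists(path)) stop("file not found: '", path, "'", call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("rank", "gene_id", "score") %in% colnames(df))) {
    stop("'", path, "' is not a gene-ranking file", call. = FALSE)
  }
  df$gene_id <- as.character(df$gene_id)
  df
}
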