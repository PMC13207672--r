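#' Write an expression dataset as MTX + TSVs
#'
#' Emits `matrix.mtx`, `genes.tsv`, `barcodes.tsv`, a `metadata.csv` with
#' the observation table, and (if planted truth is attached) `truth.json`.
#'
#' @param se a \linkS4class{SummarizedExperiment} with a `counts` assay.
#' @param dir output directory (created if needed).
#' @param truth optional planted-truth list to serialize alongside.
#' @return `dir`, invisibly.
#' @export
writeExpression <- function(se, dir, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts <- SummarizedExperiment::assay(se, "counts")
  Matrix::writeMM(methods::as(Matrix::Matrix(as.matrix(counts), sparse = TRUE),
                              "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(se), file.path(dir, "genes.tsv"))
  writeLines(colnames(se), file.path(dir, "barcodes.tsv"))
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  cd <- cbind(observation_id = colnames(se), cd)
  write.csv(cd, file.path(dir, "metadata.csv"), row.names = FALSE)
  if (!is.null(truth))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' Read an expression dataset written by [writeExpression()]
#'
#' @param dir directory with `matrix.mtx`, `genes.tsv`, `barcodes.tsv` and
#'   optionally `metadata.csv`.
#' @return A \linkS4class{SummarizedExperiment} with a `counts` assay.
#' @export
readExpression <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  rownames(m) <- readLines(file.path(dir, "genes.tsv"))
  colnames(m) <- readLines(file.path(dir, "barcodes.tsv"))
  cd <- NULL
  metaPath <- file.path(dir, "metadata.csv")
  if (file.exists(metaPath)) {
    meta <- read.csv(metaPath, stringsAsFactors = FALSE)
    rownames(meta) <- meta$observation_id
    meta$observation_id <- NULL
    cd <- S4Vectors::DataFrame(meta[colnames(m), , drop = FALSE])
  }
  if (is.null(cd))
    SummarizedExperiment::SummarizedExperiment(assays = list(counts = m))
  else
    SummarizedExperiment::SummarizedExperiment(assays = list(counts = m),
                                               colData = cd)
}

#' Write a ScoreTable as CSV
#'
#' One row per observation (`observation_id` column), one column per
#' signature.
#'
#' @param scores a [ScoreTable-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeScores <- function(scores, path) {
  stopifnot(is(scores, "ScoreTable"))
  m <- scoreMatrix(scores)
  out <- cbind(data.frame(observation_id = rownames(m)), as.data.frame(m))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
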