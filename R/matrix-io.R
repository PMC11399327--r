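# Matrix Market output of isoform count matrices, 10x-style triplet layout.

#' Write an isoform count matrix to a Matrix Market directory
#'
#' Emits `matrix.mtx`, `features.tsv` (`transcript_id`, `gene_id`) and
#' `barcodes.tsv`, plus a `run_report.json` when a report is supplied.
#'
#' @param m An `IsoformCountMatrix` (or bare `dgCMatrix`).
#' @param dir Output directory (created).
#' @param features Optional data.table mapping `transcript_id` to
#'   `gene_id`; defaults to repeating the transcript id.
#' @param report Optional list written as JSON.
#' @return `dir`, invisibly.
#' @export
write_isoform_matrix <- function(m, dir, features = NULL, report = NULL) {
  counts <- if (inherits(m, "IsoformCountMatrix")) m$counts else m
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(counts, "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  if (is.null(features))
    features <- data.table::data.table(transcript_id = rownames(counts),
                                       gene_id = rownames(counts))
  features <- features[match(rownames(counts), features$transcript_id), ]
  data.table::fwrite(features, file.path(dir, "features.tsv"),
                     sep = "\t", col.names = FALSE, quote = FALSE)
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  if (!is.null(report))
    jsonlite::write_json(report, file.path(dir, "run_report.json"),
                         auto_unbox = TRUE, null = "null")
  invisible(dir)
}

#' Read an isoform count matrix written by [write_isoform_matrix()]
#'
#' @param dir Directory holding `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv`.
#' @return List with `counts` (`dgCMatrix`, dimnames set) and `features`.
#' @export
read_isoform_matrix <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  features <- data.table::fread(file.path(dir, "features.tsv"), header = FALSE,
                                col.names = c("transcript_id", "gene_id"))
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  dimnames(counts) <- list(features$transcript_id, barcodes)
  list(counts = counts, features = features)
}
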