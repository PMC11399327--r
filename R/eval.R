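# Spike-in benchmarking: detection sensitivity, full-length feature
# accuracy, expected-vs-observed abundance correlation, and replicate
# correlation.

.counts_of <- function(m) if (inherits(m, "IsoformCountMatrix")) m$counts else m

# collapse transcript ids to indistinguishable-group representatives
.group_rep <- function(ids, indistinguishable) {
  rep_of <- stats::setNames(ids, ids)
  for (grp in indistinguishable) {
    r <- sort(grp)[1L]
    rep_of[intersect(grp, ids)] <- r
  }
  rep_of
}

#' Isoform detection sensitivity
#'
#' Fraction of ground-truth isoforms (those with at least one simulated
#' molecule) detected with a total UMI count of at least `min_umis`.
#' Transcripts whose annotated feature sets are identical (see
#' [build_feature_index()]) cannot be told apart and are counted as one
#' detectable unit.
#'
#' @param truth Character vector of transcript ids with >= 1 simulated
#'   molecule.
#' @param matrix An `IsoformCountMatrix` (or count matrix with transcript
#'   rownames).
#' @param min_umis Detection threshold (default 1).
#' @param indistinguishable Optional list of identical-feature transcript
#'   groups (e.g. `index$indistinguishable`).
#' @return Fraction in `[0, 1]`, with attributes `n_truth` and
#'   `n_detected` (unit counts).
#' @export
sensitivity <- function(truth, matrix, min_umis = 1,
                        indistinguishable = list()) {
  if (length(truth) == 0L) stop("empty truth set")
  counts <- .counts_of(matrix)
  tot <- Matrix::rowSums(counts)
  detected_tx <- rownames(counts)[tot >= min_umis]
  rep_of <- .group_rep(unique(c(truth, detected_tx)), indistinguishable)
  truth_units <- unique(rep_of[truth])
  detected_units <- intersect(unique(rep_of[detected_tx]), truth_units)
  structure(length(detected_units) / length(truth_units),
            n_truth = length(truth_units), n_detected = length(detected_units))
}

#' Per-UMI full-length feature accuracy
#'
#' Fraction of assigned UMIs whose assigned transcript equals the
#' generating transcript. Assignments within an indistinguishable group of
#' the generating transcript count as correct. Truth keys carried by two
#' molecules of different isoforms (UMI collisions) cannot be scored and
#' are dropped.
#'
#' @param assignments data.table with `cb`, `gene_id`, `umi`,
#'   `transcript_id` (one row per assigned UMI).
#' @param truth data.table with `cb`, `umi`, `gene_id`, `transcript_id`
#'   (the generating molecule table).
#' @param indistinguishable Optional list of identical-feature groups.
#' @return Fraction in `[0, 1]` with attributes `n_scored`, `n_correct`.
#' @export
feature_accuracy <- function(assignments, truth, indistinguishable = list()) {
  a <- data.table::as.data.table(assignments)
  tr <- data.table::as.data.table(truth)
  if (nrow(a) == 0L) stop("no assigned UMIs to score")
  tr <- unique(tr[, c("cb", "umi", "gene_id", "transcript_id")])
  # drop truth keys hit by molecules of two different isoforms
  nkey <- tr[, list(n = .N), by = c("cb", "umi", "gene_id")]
  tr <- tr[nkey[nkey$n == 1L], on = c("cb", "umi", "gene_id")]
  j <- tr[a, on = c("cb", "umi", "gene_id"), nomatch = 0L]
  if (nrow(j) == 0L) stop("no assigned UMIs matched the truth table")
  ids <- unique(c(j$transcript_id, j$i.transcript_id))
  rep_of <- .group_rep(ids, indistinguishable)
  correct <- rep_of[j$transcript_id] == rep_of[j$i.transcript_id]
  structure(mean(correct), n_scored = nrow(j), n_correct = sum(correct))
}

#' Expected-vs-observed spike-in abundance correlation
#'
#' Pearson correlation, on the `log2(x + 1)` scale by default, between the
#' expected abundance of each spike-in species and its total observed UMI
#' count (zeros included).
#'
#' @param truth data.table with `transcript_id` and `expected_abundance`
#'   (one row per species).
#' @param matrix An `IsoformCountMatrix` (or count matrix).
#' @param log_base,offset Transform parameters (defaults 2 and 1).
#' @return Pearson correlation coefficient.
#' @export
abundance_correlation <- function(truth, matrix, log_base = 2, offset = 1) {
  counts <- .counts_of(matrix)
  tot <- Matrix::rowSums(counts)
  obs <- tot[match(truth$transcript_id, names(tot))]
  obs[is.na(obs)] <- 0
  if (length(obs) < 3L) stop("need >= 3 species")
  x <- log(truth$expected_abundance + offset, base = log_base)
  y <- log(obs + offset, base = log_base)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(x, y)
}

#' Replicate correlation of spike-in totals
#'
#' Pearson correlation of log-transformed per-species total counts between
#' two independent runs, over the shared species universe.
#'
#' @param matrixA,matrixB Count matrices (or `IsoformCountMatrix`) with
#'   transcript rownames.
#' @param species Optional character vector restricting the universe.
#' @param log_base,offset Transform parameters.
#' @return Pearson correlation coefficient.
#' @export
replicate_correlation <- function(matrixA, matrixB, species = NULL,
                                  log_base = 2, offset = 1) {
  ca <- .counts_of(matrixA); cb_ <- .counts_of(matrixB)
  shared <- intersect(rownames(ca), rownames(cb_))
  if (!is.null(species)) shared <- intersect(shared, species)
  if (length(shared) < 3L) stop("empty or too-small shared species universe")
  x <- log(Matrix::rowSums(ca)[shared] + offset, base = log_base)
  y <- log(Matrix::rowSums(cb_)[shared] + offset, base = log_base)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(x, y)
}

#' Assemble a spike-in evaluation report
#'
#' @param truth_detect Transcript ids with >= 1 simulated molecule.
#' @param matrix Pipeline output matrix.
#' @param assignments Assignment table (for accuracy).
#' @param molecule_truth Molecule truth table.
#' @param abundance_truth Species table with `expected_abundance`.
#' @param indistinguishable Identical-feature groups.
#' @param matrixB Optional replicate matrix.
#' @param min_umis Detection threshold.
#' @return List of class `EvalReport`.
#' @export
eval_report <- function(truth_detect, matrix, assignments, molecule_truth,
                        abundance_truth = NULL, indistinguishable = list(),
                        matrixB = NULL, min_umis = 1) {
  sens <- sensitivity(truth_detect, matrix, min_umis, indistinguishable)
  acc <- feature_accuracy(assignments, molecule_truth, indistinguishable)
  r <- list(n_truth_isoforms = attr(sens, "n_truth"),
            n_detected = attr(sens, "n_detected"),
            sensitivity = as.numeric(sens),
            feature_accuracy = as.numeric(acc),
            pearson_expected_observed =
              if (!is.null(abundance_truth))
                abundance_correlation(abundance_truth, matrix) else NULL,
            pearson_replicates =
              if (!is.null(matrixB))
                replicate_correlation(matrix, matrixB) else NULL)
  structure(r[!vapply(r, is.null, TRUE)], class = "EvalReport")
}

#' @export
print.EvalReport <- function(x, ...) {
  cat("EvalReport\n")
  cat(sprintf("  detected %d / %d isoform units (sensitivity %.3f)\n",
              x$n_detected, x$n_truth_isoforms, x$sensitivity))
  cat(sprintf("  per-UMI feature accuracy %.4f\n", x$feature_accuracy))
  if (!is.null(x$pearson_expected_observed))
    cat(sprintf("  expected-vs-observed r = %.4f\n", x$pearson_expected_observed))
  if (!is.null(x$pearson_replicates))
    cat(sprintf("  replicate r = %.4f\n", x$pearson_replicates))
  invisible(x)
}
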