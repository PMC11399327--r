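# Isoform assignment: ingest tagged alignments from the paired TSS/TES
# libraries, collapse by (cell barcode, gene, UMI), match observed features
# against the annotation index, assign directly where unique and by
# maximal probability otherwise.

utils::globalVariables(c(
  ".", "frag_id", "bstart", "bend", "gid", "end_class", "fstart", "fend",
  "gene_id", "transcript_id", "cb", "umi", "tss", "tes", "obs5", "obs3",
  "n_matched", "njunc", "score", "jstart", "jend", "i.start", "i.end",
  "method", "N", "gstrand", "strand", "both", "s", "e", "start", "end",
  "is_tss", "is_tes", "n_tss", "n_tes", "end_classes_present", "mn", "mx"))

#' Read tagged alignments from a SAM/BAM file
#'
#' Ingests aligned fragments carrying cell-barcode/UMI/gene tags (defaults
#' `CB`/`UB`/`GX`). SAM input is converted to BAM on the fly. Split
#' alignments (N CIGAR operations) become multi-block fragments.
#'
#' @param path SAM or BAM file.
#' @param end_class `"TSS"` or `"TES"`: which library the file came from.
#' @param tags Character vector of the barcode, UMI and gene tag names.
#' @return List with `fragments` (data.table: `frag_id`, `read_id`, `cb`,
#'   `umi`, `gene_id`, `end_class`, `chrom`, `strand`) and `blocks`
#'   (data.table: `frag_id`, `bstart`, `bend`; 0-based half-open).
#' @export
read_tagged_alignments <- function(path, end_class = c("TSS", "TES"),
                                   tags = c(cb = "CB", umi = "UB", gene = "GX")) {
  end_class <- match.arg(end_class)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  } else bam <- path
  param <- Rsamtools::ScanBamParam(what = c("qname", "flag"),
                                   tag = unname(tags))
  gal <- GenomicAlignments::readGAlignments(bam, param = param)
  mc <- S4Vectors::mcols(gal)
  get_tag <- function(nm) {
    v <- mc[[tags[[nm]]]]
    if (is.null(v)) stop("tag ", tags[[nm]], " missing from ", path)
    as.character(v)
  }
  n <- length(gal)
  frags <- data.table::data.table(
    frag_id = seq_len(n),
    read_id = mc$qname,
    cb = get_tag("cb"), umi = get_tag("umi"), gene_id = get_tag("gene"),
    end_class = end_class,
    chrom = as.character(GenomicAlignments::seqnames(gal)),
    strand = as.character(GenomicAlignments::strand(gal)))
  grl <- GenomicAlignments::grglist(gal)
  u <- unlist(grl, use.names = FALSE)
  blocks <- data.table::data.table(
    frag_id = rep(seq_len(n), S4Vectors::elementNROWS(grl)),
    bstart = GenomicRanges::start(u) - 1L,
    bend = GenomicRanges::end(u))
  list(fragments = frags, blocks = blocks)
}

#' Group aligned fragments by (cell, gene, UMI)
#'
#' All fragments sharing `(cb, gene_id, umi)` derive from one cDNA molecule
#' and form the unit of isoform assignment. Fragments with an unassigned
#' (`NA`, `"-"`, empty) or multi-gene (`;`-separated) gene tag are dropped
#' and counted.
#'
#' @param fragments Fragment data.table (see [read_tagged_alignments()]).
#' @return List with `fragments` (the kept rows, with a `gid` group id
#'   column), `groups` (data.table: `gid`, `cb`, `gene_id`, `umi`,
#'   `end_classes_present`), `dropped` (named counts).
#' @export
group_umis <- function(fragments) {
  f <- data.table::as.data.table(fragments)
  bad_na <- is.na(f$gene_id) | f$gene_id %in% c("", "-")
  bad_multi <- !bad_na & grepl(";", f$gene_id, fixed = TRUE)
  dropped <- c(no_gene = sum(bad_na), multi_gene = sum(bad_multi))
  f <- f[!(bad_na | bad_multi)]
  data.table::setorder(f, cb, gene_id, umi, frag_id)
  f[, gid := .GRP, by = .(cb, gene_id, umi)]
  f[, is_tss := end_class == "TSS"]
  f[, is_tes := !is_tss]
  groups <- f[, .(n_tss = sum(is_tss), n_tes = sum(is_tes)),
              by = .(gid, cb, gene_id, umi)]
  groups[, end_classes_present := data.table::fcase(
    n_tss > 0L & n_tes > 0L, "TSS,TES",
    n_tss > 0L, "TSS", default = "TES")]
  f[, c("is_tss", "is_tes") := NULL]
  list(fragments = f, groups = groups, dropped = dropped)
}

#' Match a UMI group's observed features against annotated isoforms
#'
#' Starts from all isoforms of the group's gene and intersects with (i)
#' isoforms whose annotated TSS lies within tolerance of the observed 5'
#' terminus of the TSS-library fragments (when present), (ii) likewise for
#' the TES, (iii) isoforms containing every splice junction implied by
#' split-aligned blocks, and excludes (iv) isoforms spliced where a
#' fragment block aligns contiguously across the annotated intron.
#'
#' @param group A list describing one UMI group: `gene_id`, and `fragments`
#'   -- a list of fragments, each a list with `end_class` and `blocks` (a
#'   2-column 0-based half-open matrix).
#' @param index A [build_feature_index()] object.
#' @return List with `compat` (sorted character vector of compatible
#'   transcript ids) and `evidence` (`tss_matched`, `tes_matched`,
#'   `junctions_matched`), or a list with `reason = "gene_not_indexed"`.
#' @export
match_features <- function(group, index) {
  g <- group$gene_id
  gi <- index$genes[index$genes$gene_id == g]
  if (nrow(gi) == 0L)
    return(list(compat = character(0), reason = "gene_not_indexed",
                evidence = NULL))
  strand <- gi$strand[1L]
  compat <- sort(index$tx$transcript_id[index$tx$gene_id == g])
  ev <- list(tss_matched = FALSE, tes_matched = FALSE, junctions_matched = 0L)

  frs <- group$fragments
  cls <- vapply(frs, `[[`, "", "end_class")
  starts <- lapply(frs, function(fr) fr$blocks[, 1L])
  ends <- lapply(frs, function(fr) fr$blocks[, 2L])
  obs_terminus <- function(which_cls, five_prime) {
    sel <- cls == which_cls
    if (!any(sel)) return(NA_real_)
    if ((strand == "+") == five_prime)
      min(unlist(starts[sel])) else max(unlist(ends[sel]))
  }
  obs5 <- obs_terminus("TSS", five_prime = TRUE)
  obs3 <- obs_terminus("TES", five_prime = FALSE)
  if (!is.na(obs5)) {
    compat <- intersect(compat, query_end(index, g, obs5, "TSS"))
    ev$tss_matched <- length(compat) > 0L
  }
  if (!is.na(obs3)) {
    compat <- intersect(compat, query_end(index, g, obs3, "TES"))
    ev$tes_matched <- length(compat) > 0L
  }
  # observed junctions: gaps between consecutive blocks of a fragment
  juncs <- unique(do.call(rbind, lapply(frs, function(fr) {
    b <- fr$blocks
    if (nrow(b) < 2L) return(NULL)
    cbind(b[-nrow(b), 2L], b[-1L, 1L])
  })))
  if (!is.null(juncs) && nrow(juncs)) {
    ev$junctions_matched <- nrow(juncs)
    for (k in seq_len(nrow(juncs)))
      compat <- intersect(compat,
                          query_junction(index, g, juncs[k, 1L], juncs[k, 2L]))
  }
  # contiguous alignment across an annotated intron excludes the isoform
  # (blocks never overlap an intron they splice across: they abut it)
  ii <- index$introns[index$introns$gene_id == g]
  if (nrow(ii) && length(compat)) {
    bs <- unlist(starts); be <- unlist(ends)
    hit <- vapply(seq_len(nrow(ii)), function(k)
      any(bs < ii$end[k] & be > ii$start[k]), TRUE)
    compat <- setdiff(compat, unique(ii$transcript_id[hit]))
  }
  list(compat = sort(compat), evidence = ev)
}

# Vectorized feature matching over all groups at once (same rule set as
# match_features; cross-checked against it in the test suite).
# Returns list(compat = data.table(gid, transcript_id), groups = info dt).
match_features_all <- function(fragments, blocks, index) {
  f <- fragments
  b <- blocks[f[, .(frag_id, gid, end_class)], on = "frag_id", nomatch = 0L]
  ginfo <- f[, .(gene_id = gene_id[1L]), by = gid]
  ginfo <- index$genes[ginfo, on = "gene_id"]
  data.table::setnames(ginfo, "strand", "gstrand")

  # fragment terminal extents -> group observed 5'/3' termini (strand-aware)
  fext <- b[, .(fstart = min(bstart), fend = max(bend)),
            by = .(frag_id, gid, end_class)]
  fext <- fext[ginfo[, .(gid, gstrand)], on = "gid"]
  o5 <- fext[end_class == "TSS",
             .(mn = min(fstart), mx = max(fend),
               gstrand = data.table::first(gstrand)), by = gid]
  o5[, obs5 := data.table::fifelse(gstrand == "+", mn, mx)]
  o5 <- o5[, .(gid, obs5)]
  o3 <- fext[end_class == "TES",
             .(mn = min(fstart), mx = max(fend),
               gstrand = data.table::first(gstrand)), by = gid]
  o3[, obs3 := data.table::fifelse(gstrand == "+", mx, mn)]
  o3 <- o3[, .(gid, obs3)]
  ginfo <- o5[ginfo, on = "gid"]
  ginfo <- o3[ginfo, on = "gid"]

  # observed junctions per group: gaps between consecutive blocks of a
  # fragment (vectorized via shift within the frag_id-sorted block table)
  data.table::setorder(b, frag_id, bstart)
  nxt_start <- data.table::shift(b$bstart, -1L)
  same_frag <- data.table::shift(b$frag_id, -1L) == b$frag_id
  jrows <- which(!is.na(same_frag) & same_frag)
  gj <- unique(data.table::data.table(gid = b$gid[jrows],
                                      jstart = b$bend[jrows],
                                      jend = nxt_start[jrows]))
  njunc_g <- gj[, .(njunc = .N), by = gid]
  ginfo <- njunc_g[ginfo, on = "gid"]
  ginfo[is.na(njunc), njunc := 0L]

  # candidate (group x transcript) pairs for the group's gene
  cand <- index$tx[ginfo, on = "gene_id", allow.cartesian = TRUE]
  cand <- cand[!is.na(transcript_id)]
  tol <- index$tolerance_bp
  cand <- cand[is.na(obs5) | abs(tss - obs5) <= tol]
  cand <- cand[is.na(obs3) | abs(tes - obs3) <= tol]

  # junction containment: every observed junction must be annotated in tx
  if (nrow(gj)) {
    gj2 <- gj[ginfo[, .(gid, gene_id)], on = "gid", nomatch = 0L]
    jm <- merge(gj2, index$junctions,
                by.x = c("gene_id", "jstart", "jend"),
                by.y = c("gene_id", "start", "end"),
                allow.cartesian = TRUE)[, .(n_matched = .N),
                                        by = .(gid, transcript_id)]
    cand <- jm[cand, on = c("gid", "transcript_id")]
    cand[is.na(n_matched), n_matched := 0L]
    cand <- cand[n_matched == njunc]
  }

  # exclusion: a block overlapping an annotated intron of tx (not explained
  # by an observed junction at exactly that intron) rules the isoform out
  if (nrow(index$introns) && nrow(cand)) {
    gb <- unique(b[, .(gid, bstart, bend)])
    gb <- gb[ginfo[, .(gid, gene_id)], on = "gid", nomatch = 0L]
     intr <- data.table::copy(index$introns)
    # closed-interval keys for foverlaps; strict overlap of half-open ivs
    gb[, `:=`(s = bstart, e = bend - 1L)]
    intr[, `:=`(s = start, e = end - 1L)]
    data.table::setkey(intr, gene_id, s, e)
    ov <- data.table::foverlaps(gb, intr, by.x = c("gene_id", "s", "e"),
                                nomatch = 0L)
    excl <- unique(ov[, .(gid, transcript_id)])
    cand <- cand[!excl, on = c("gid", "transcript_id")]
  }
  list(compat = cand[, .(gid, transcript_id)], groups = ginfo)
}

#' Direct assignment from a compatibility set
#'
#' @param compat Character vector of compatible transcript ids.
#' @return List of class `Assignment`: `method` is `"direct"` when exactly
#'   one isoform is compatible, `"ambiguous"` when several are (deferred to
#'   [assign_probabilistic()]), `"unassigned"` when none is.
#' @export
assign_direct <- function(compat) {
  if (length(compat) == 1L)
    structure(list(transcript_id = compat, method = "direct"),
              class = "Assignment")
  else if (length(compat) > 1L)
    structure(list(transcript_id = sort(compat), method = "ambiguous"),
              class = "Assignment")
  else
    structure(list(transcript_id = NA_character_, method = "unassigned",
                   reason = "no_compatible"), class = "Assignment")
}

#' Maximal-probability rescue of ambiguous UMIs
#'
#' For each ambiguous UMI, the probability of each isoform in its
#' compatibility set is proportional to that isoform's directly assigned
#' UMI count within the same gene (pooled across cells) plus a pseudocount
#' of 1. The UMI is assigned to the arg-max; ties break to the
#' lexicographically smallest transcript id.
#'
#' @param ambiguous List of ambiguous `Assignment`s, each with a
#'   `transcript_id` vector (the compatibility set).
#' @param direct_counts Named numeric vector: directly assigned UMI counts
#'   per transcript id (pooled across cells within genes).
#' @param pseudocount Added to every count (default 1).
#' @return List of `Assignment`s with `method = "probabilistic"`.
#' @export
assign_probabilistic <- function(ambiguous, direct_counts, pseudocount = 1) {
  lapply(ambiguous, function(a) {
    set <- sort(a$transcript_id)
    sc <- unname(direct_counts[set])
    sc[is.na(sc)] <- 0
    sc <- sc + pseudocount
    k <- which.max(sc)  # which.max takes the first (lexicographic) tie
    structure(list(transcript_id = set[k], method = "probabilistic",
                   probability = sc[k] / sum(sc)),
              class = "Assignment")
  })
}

#' Build a sparse isoform-by-cell count matrix from assignments
#'
#' @param assignments data.table with columns `cb`, `transcript_id`,
#'   `method` (one row per assigned UMI; `method` in
#'   `c("direct", "probabilistic")`).
#' @param transcript_ids Row universe (default: observed transcripts).
#' @param barcodes Column universe (default: observed barcodes).
#' @return Object of class `IsoformCountMatrix`: list with `counts` (total,
#'   `dgCMatrix`), `direct` and `probabilistic` (provenance matrices,
#'   `counts = direct + probabilistic`), and a `summary` of assigned UMIs.
#' @export
build_matrix <- function(assignments, transcript_ids = NULL, barcodes = NULL) {
  a <- data.table::as.data.table(assignments)
  if (is.null(transcript_ids)) transcript_ids <- sort(unique(a$transcript_id))
  if (is.null(barcodes)) barcodes <- sort(unique(a$cb))
  mk <- function(sub) {
    if (nrow(sub) == 0L)
      return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                  dims = c(length(transcript_ids), length(barcodes)),
                                  dimnames = list(transcript_ids, barcodes)))
    Matrix::sparseMatrix(
      i = match(sub$transcript_id, transcript_ids),
      j = match(sub$cb, barcodes), x = rep(1, nrow(sub)),
      dims = c(length(transcript_ids), length(barcodes)),
      dimnames = list(transcript_ids, barcodes))
  }
  direct <- mk(a[a$method == "direct"])
  prob <- mk(a[a$method == "probabilistic"])
  structure(list(counts = direct + prob, direct = direct, probabilistic = prob,
                 summary = c(assigned = nrow(a),
                             direct = sum(a$method == "direct"),
                             probabilistic = sum(a$method == "probabilistic"))),
            class = "IsoformCountMatrix")
}

#' @export
print.IsoformCountMatrix <- function(x, ...) {
  cat(sprintf("IsoformCountMatrix: %d isoforms x %d cells, %d UMIs (%d direct, %d probabilistic)\n",
              nrow(x$counts), ncol(x$counts), as.integer(sum(x$counts)),
              as.integer(sum(x$direct)), as.integer(sum(x$probabilistic))))
  invisible(x)
}

#' Run the isoform identification pipeline end to end
#'
#' Merges tagged alignments from the TSS and TES libraries, collapses reads
#' by (cell, gene, UMI), matches observed features against the annotation,
#' assigns UMIs directly where a single isoform is compatible and by
#' maximal probability otherwise, and builds the isoform-by-cell matrix.
#' Deterministic given inputs and configuration, irrespective of input
#' record order.
#'
#' @param tss,tes SAM/BAM paths of the TSS- and TES-library alignments
#'   (tagged with `CB`/`UB`/`GX`-style tags).
#' @param annotation GTF path, a list of `TranscriptModel`, or a
#'   `FeatureIndex`.
#' @param tolerance_bp End-matching tolerance (default 50; ignored when a
#'   prebuilt `FeatureIndex` is supplied).
#' @param require_both_ends If `TRUE`, only UMI groups observed in both
#'   libraries are assignable (default `FALSE`).
#' @param rescue Apply maximal-probability rescue to ambiguous UMIs
#'   (default `TRUE`).
#' @param tags Tag names for barcode/UMI/gene (defaults `CB`, `UB`, `GX`).
#' @return List of class `pipeline_result` with `matrix`
#'   (`IsoformCountMatrix`), `assignments` (data.table: `cb`, `gene_id`,
#'   `umi`, `transcript_id`, `method`), `report` (counts by category) and
#'   `index`.
#' @export
run_pipeline <- function(tss, tes, annotation, tolerance_bp = 50,
                         require_both_ends = FALSE, rescue = TRUE,
                         tags = c(cb = "CB", umi = "UB", gene = "GX")) {
  index <- if (inherits(annotation, "FeatureIndex")) annotation
           else if (is.character(annotation))
             build_feature_index(read_gtf(annotation), tolerance_bp)
           else build_feature_index(annotation, tolerance_bp)
  a1 <- read_tagged_alignments(tss, "TSS", tags)
  a2 <- read_tagged_alignments(tes, "TES", tags)
  a2$fragments[, frag_id := frag_id + nrow(a1$fragments)]
  a2$blocks[, frag_id := frag_id + nrow(a1$fragments)]
  frags <- data.table::rbindlist(list(a1$fragments, a2$fragments))
  blocks <- data.table::rbindlist(list(a1$blocks, a2$blocks))

  gu <- group_umis(frags)
  f <- gu$fragments
  # fragments must match the annotated strand of their gene
  f <- index$genes[f, on = "gene_id"]
  data.table::setnames(f, c("strand", "i.strand"), c("gstrand", "strand"),
                       skip_absent = TRUE)
  n_strand_drop <- sum(is.na(f$gstrand) | f$strand != f$gstrand)
  unknown_gene <- unique(f$gene_id[is.na(f$gstrand)])
  f <- f[!is.na(gstrand) & strand == gstrand]
  f[, gid := .GRP, by = .(cb, gene_id, umi)]  # re-key after filtering
  blocks <- blocks[blocks$frag_id %in% f$frag_id]

  report <- list(n_fragments = nrow(frags),
                 dropped_no_gene = unname(gu$dropped["no_gene"]),
                 dropped_multi_gene = unname(gu$dropped["multi_gene"]),
                 dropped_strand_or_unknown_gene = n_strand_drop,
                 unknown_genes = unknown_gene)
  empty_assign <- data.table::data.table(cb = character(), gene_id = character(),
                                         umi = character(), transcript_id = character(),
                                         method = character())
  if (nrow(f) == 0L) {
    mat <- build_matrix(empty_assign, transcript_ids = sort(index$tx$transcript_id))
    report <- c(report, list(n_groups = 0L, assigned_direct = 0L,
                             assigned_probabilistic = 0L, unassigned = 0L,
                             ambiguous_remaining = 0L))
    return(structure(list(matrix = mat, assignments = empty_assign,
                          report = report, index = index),
                     class = "pipeline_result"))
  }
  f[, is_tss := end_class == "TSS"]
  f[, is_tes := !is_tss]
  keys <- f[, .(n_tss = sum(is_tss), n_tes = sum(is_tes)),
            by = .(gid, cb, gene_id, umi)]
  keys[, both := n_tss > 0L & n_tes > 0L]
  mf <- match_features_all(f, blocks, index)
  compat <- mf$compat
  if (require_both_ends) compat <- compat[keys[both == TRUE], on = "gid",
                                          nomatch = 0L][, .(gid, transcript_id)]
  ncomp <- compat[, .N, by = gid]
  keys <- ncomp[keys, on = "gid"]
  keys[is.na(N), N := 0L]

  direct <- compat[keys[N == 1L], on = "gid", nomatch = 0L]
  direct_counts <- direct[, .N, by = transcript_id]
  dc <- stats::setNames(as.numeric(direct_counts$N), direct_counts$transcript_id)

  amb_gids <- keys[N > 1L, gid]
  amb_sets <- compat[data.table::data.table(gid = amb_gids), on = "gid"]
  if (rescue && length(amb_gids)) {
    amb_list <- split(amb_sets$transcript_id, amb_sets$gid)
    picks <- assign_probabilistic(
      lapply(amb_list, function(s) list(transcript_id = s)), dc)
    prob <- data.table::data.table(
      gid = as.integer(names(amb_list)),
      transcript_id = vapply(picks, `[[`, "", "transcript_id"),
      method = "probabilistic")
  } else {
    prob <- data.table::data.table(gid = integer(), transcript_id = character(),
                                   method = character())
  }
  assigns <- data.table::rbindlist(list(
    direct[, .(gid, transcript_id, method = "direct")], prob))
  assigns <- keys[, .(gid, cb, gene_id, umi)][assigns, on = "gid"]
  data.table::setorder(assigns, cb, gene_id, umi, transcript_id)
  mat <- build_matrix(assigns[, .(cb, transcript_id, method)],
                      transcript_ids = sort(index$tx$transcript_id),
                      barcodes = sort(unique(keys$cb)))
  report <- c(report, list(
    n_groups = nrow(keys),
    assigned_direct = sum(keys$N == 1L),
    assigned_probabilistic = nrow(prob),
    unassigned = sum(keys$N == 0L),
    ambiguous_remaining = sum(keys$N > 1L) - nrow(prob)))
  structure(list(matrix = mat,
                 assignments = assigns[, .(cb, gene_id, umi, transcript_id, method)],
                 report = report, index = index),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  r <- x$report
  cat(sprintf(paste0("pipeline_result: %d fragments -> %d UMI groups ",
                     "(%d direct, %d probabilistic, %d unassigned)\n"),
              r$n_fragments, r$n_groups, r$assigned_direct,
              r$assigned_probabilistic, r$unassigned))
  invisible(x)
}
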