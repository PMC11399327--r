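# Annotation model: transcript structures, feature index, promoter windows.
#
# All internal coordinates are 0-based half-open; GTF input/output converts
# at the boundary (GTF is 1-based inclusive).

#' Construct a transcript model
#'
#' A `TranscriptModel` describes one annotated isoform: its gene, strand,
#' ordered exon chain and the strand-aware transcription start site (TSS)
#' and transcription end site (TES).
#'
#' @param transcript_id,gene_id Character scalars.
#' @param chrom Chromosome / contig name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column numeric matrix of exon intervals, 0-based
#'   half-open, rows sorted by start and pairwise disjoint.
#' @return An object of class `TranscriptModel` with fields
#'   `transcript_id`, `gene_id`, `chrom`, `strand`, `exons`, `tss`, `tes`.
#'   On the `+` strand the TSS is the start of the first exon and the TES
#'   the end of the last exon; on the `-` strand the reverse.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons) {
  stopifnot(is.character(transcript_id), length(transcript_id) == 1L,
            is.character(gene_id), length(gene_id) == 1L,
            strand %in% c("+", "-"))
  exons <- matrix(as.numeric(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) == 0L) stop("transcript '", transcript_id, "' has zero exons")
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (any(exons[, 2L] <= exons[, 1L]))
    stop("transcript '", transcript_id, "' has an empty or inverted exon")
  if (nrow(exons) > 1L && any(exons[-1L, 1L] < exons[-nrow(exons), 2L]))
    stop("transcript '", transcript_id, "' has overlapping exons")
  tss <- unname(if (strand == "+") exons[1L, 1L] else exons[nrow(exons), 2L])
  tes <- unname(if (strand == "+") exons[nrow(exons), 2L] else exons[1L, 1L])
  if (tss == tes) stop("degenerate transcript: tss == tes")
  structure(
    list(transcript_id = transcript_id, gene_id = gene_id, chrom = chrom,
         strand = strand, exons = exons, tss = tss, tes = tes),
    class = "TranscriptModel")
}

#' @export
print.TranscriptModel <- function(x, ...) {
  cat(sprintf("TranscriptModel %s (gene %s) %s:%s %d exon(s), tss=%d tes=%d\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand,
              nrow(x$exons), as.integer(x$tss), as.integer(x$tes)))
  invisible(x)
}

# intron intervals of a transcript (0-based half-open); 0-row matrix if none
transcript_introns <- function(t) {
  n <- nrow(t$exons)
  if (n < 2L) return(matrix(numeric(0), ncol = 2L,
                            dimnames = list(NULL, c("start", "end"))))
  cbind(start = t$exons[-n, 2L], end = t$exons[-1L, 1L])
}

transcript_length <- function(t) sum(t$exons[, 2L] - t$exons[, 1L])

#' Read transcript models from a GTF file
#'
#' Exon features are grouped by `transcript_id`; coordinates are converted
#' from the 1-based inclusive GTF convention to 0-based half-open.
#'
#' @param path Path to a GTF file (GENCODE-style attributes; `exon`
#'   features must carry `gene_id` and `transcript_id`).
#' @return Named list of [transcript_model()] objects (one per transcript).
#' @export
read_gtf <- function(path) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf < 9L))
    stop("malformed GTF line ", body[which(nf < 9L)[1L]], " in ", path,
         ": expected 9 tab-separated fields")
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  if (length(ex) == 0L) return(list())
  dt <- data.table::data.table(
    transcript_id = as.character(ex$transcript_id),
    gene_id       = as.character(ex$gene_id),
    chrom         = as.character(GenomicRanges::seqnames(ex)),
    strand        = as.character(GenomicRanges::strand(ex)),
    start         = GenomicRanges::start(ex) - 1L,  # to 0-based half-open
    end           = GenomicRanges::end(ex))
  declared <- unique(as.character(gr$transcript_id[gr$type %in% c("transcript", "mRNA")]))
  missing_tx <- setdiff(declared, dt$transcript_id)
  if (length(missing_tx))
    warning("rejected transcript(s) with zero exons: ",
            paste(missing_tx, collapse = ", "))
  tx <- split(dt, by = "transcript_id", keep.by = TRUE)
  out <- lapply(tx, function(d)
    transcript_model(d$transcript_id[1L], d$gene_id[1L], d$chrom[1L],
                     d$strand[1L], cbind(d$start, d$end)))
  out[order(names(out))]
}

#' Write transcript models to a GTF file
#'
#' Inverse of [read_gtf()]: emits one `exon` feature per exon with
#' `gene_id`/`transcript_id` attributes, converting back to 1-based
#' inclusive coordinates.
#'
#' @param transcripts List of `TranscriptModel`.
#' @param path Output GTF path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(transcripts, path) {
  dt <- data.table::rbindlist(lapply(transcripts, function(t)
    data.table::data.table(chrom = t$chrom, start = t$exons[, 1L] + 1L,
                           end = t$exons[, 2L], strand = t$strand,
                           gene_id = t$gene_id, transcript_id = t$transcript_id)))
  gr <- GenomicRanges::GRanges(
    seqnames = dt$chrom,
    ranges = IRanges::IRanges(start = dt$start, end = dt$end),
    strand = dt$strand)
  gr$source <- "pairiso"
  gr$type <- "exon"
  gr$gene_id <- dt$gene_id
  gr$transcript_id <- dt$transcript_id
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Build a per-gene feature index over transcript models
#'
#' Indexes, per gene, the annotated TSS and TES positions, splice junctions
#' (intron intervals) and intron bodies, with the inverse map from each
#' feature to the transcripts carrying it. The index answers compatibility
#' queries: which isoforms of a gene have an end within `tolerance_bp` of an
#' observed terminus, or contain a given junction.
#'
#' Transcripts of a gene with identical feature sets (same TSS, TES and
#' junction set) cannot be told apart by any read; they are grouped in
#' `$indistinguishable` and evaluation counts each group once.
#'
#' @param transcripts List of `TranscriptModel`.
#' @param tolerance_bp Non-negative integer; half-width of the end-matching
#'   window (default 50).
#' @return Object of class `FeatureIndex`.
#' @export
build_feature_index <- function(transcripts, tolerance_bp = 50) {
  stopifnot(tolerance_bp >= 0)
  if (length(transcripts) == 0L) {
    empty <- data.table::data.table(gene_id = character(), transcript_id = character(),
                                    pos = numeric())
    emptyj <- data.table::data.table(gene_id = character(), transcript_id = character(),
                                     start = numeric(), end = numeric())
    return(structure(list(
      tolerance_bp = tolerance_bp, transcripts = list(),
      genes = data.table::data.table(gene_id = character(), chrom = character(),
                                     strand = character()),
      tx = data.table::data.table(gene_id = character(), transcript_id = character(),
                                  tss = numeric(), tes = numeric(), n_junctions = integer()),
      tss = empty, tes = empty, junctions = emptyj, introns = emptyj,
      indistinguishable = list()), class = "FeatureIndex"))
  }
  names(transcripts) <- vapply(transcripts, `[[`, "", "transcript_id")
  tx <- data.table::rbindlist(lapply(transcripts, function(t)
    data.table::data.table(gene_id = t$gene_id, transcript_id = t$transcript_id,
                           chrom = t$chrom, strand = t$strand,
                           tss = t$tss, tes = t$tes,
                           n_junctions = max(nrow(t$exons) - 1L, 0L))))
  data.table::setorder(tx, gene_id, transcript_id)
  junc <- data.table::rbindlist(lapply(transcripts, function(t) {
    ii <- transcript_introns(t)
    if (nrow(ii) == 0L) return(NULL)
    data.table::data.table(gene_id = t$gene_id, transcript_id = t$transcript_id,
                           start = ii[, 1L], end = ii[, 2L])
  }))
  if (is.null(junc) || nrow(junc) == 0L)
    junc <- data.table::data.table(gene_id = character(), transcript_id = character(),
                                   start = numeric(), end = numeric())
  # identical-feature groups within a gene
  sig <- vapply(transcripts, function(t) {
    ii <- transcript_introns(t)
    paste(t$gene_id, t$tss, t$tes,
          paste(ii[, 1L], ii[, 2L], sep = "-", collapse = ","), sep = "|")
  }, "")
  grp <- split(names(sig), sig)
  indist <- unname(grp[lengths(grp) > 1L])
  structure(list(
    tolerance_bp = tolerance_bp,
    transcripts = transcripts,
    genes = unique(tx[, c("gene_id", "chrom", "strand")]),
    tx = tx[, c("gene_id", "transcript_id", "tss", "tes", "n_junctions")],
    tss = tx[, list(gene_id = gene_id, transcript_id = transcript_id, pos = tss)],
    tes = tx[, list(gene_id = gene_id, transcript_id = transcript_id, pos = tes)],
    junctions = junc,
    introns = data.table::copy(junc),
    indistinguishable = indist), class = "FeatureIndex")
}

#' @export
print.FeatureIndex <- function(x, ...) {
  cat(sprintf("FeatureIndex: %d transcripts, %d genes, %d junctions, tolerance %d bp\n",
              nrow(x$tx), nrow(x$genes), nrow(x$junctions),
              as.integer(x$tolerance_bp)))
  invisible(x)
}

#' Query transcripts whose annotated end lies within tolerance of a position
#'
#' @param index A `FeatureIndex`.
#' @param gene_id Gene to query.
#' @param pos Observed terminus (0-based genomic position).
#' @param end_class `"TSS"` or `"TES"`.
#' @return Character vector of compatible transcript ids (possibly empty).
#' @export
query_end <- function(index, gene_id, pos, end_class = c("TSS", "TES")) {
  end_class <- match.arg(end_class)
  tab <- if (end_class == "TSS") index$tss else index$tes
  gid <- gene_id; p <- pos
  hits <- tab[tab$gene_id == gid & abs(tab$pos - p) <= index$tolerance_bp]
  sort(hits$transcript_id)
}

#' Query transcripts of a gene containing an exact splice junction
#'
#' @param index A `FeatureIndex`.
#' @param gene_id Gene to query.
#' @param start,end Intron interval (0-based half-open).
#' @return Character vector of transcript ids carrying the junction.
#' @export
query_junction <- function(index, gene_id, start, end) {
  gid <- gene_id; s <- start; e <- end
  hits <- index$junctions[index$junctions$gene_id == gid &
                          index$junctions$start == s & index$junctions$end == e]
  sort(hits$transcript_id)
}

#' Promoter window of a transcript
#'
#' The promoter is defined as 2000 bp upstream to 200 bp downstream of the
#' TSS, strand-aware, clamped at position 0 (and at the contig length when
#' supplied): on the `+` strand `[tss - 2000, tss + 200)`, on the `-`
#' strand `[tss - 200, tss + 2000)`.
#'
#' @param t A `TranscriptModel`.
#' @param upstream,downstream Window extents in bp (defaults 2000 and 200).
#' @param contig_length Optional right clamp.
#' @return Object of class `PromoterWindow`: list with `gene_id`,
#'   `transcript_id`, `chrom`, `strand`, `start`, `end` (0-based half-open).
#' @export
promoter_window <- function(t, upstream = 2000, downstream = 200,
                            contig_length = NULL) {
  if (t$strand == "+") {
    s <- t$tss - upstream; e <- t$tss + downstream
  } else {
    s <- t$tss - downstream; e <- t$tss + upstream
  }
  s <- max(s, 0)
  if (!is.null(contig_length)) e <- min(e, contig_length)
  structure(list(gene_id = t$gene_id, transcript_id = t$transcript_id,
                 chrom = t$chrom, strand = t$strand, start = s, end = e),
            class = "PromoterWindow")
}

#' Promoter windows for a list of transcripts, as a table
#'
#' @param transcripts List of `TranscriptModel`.
#' @inheritParams promoter_window
#' @param contig_lengths Optional named vector of contig lengths.
#' @return `data.table` with one row per transcript.
#' @export
promoter_windows <- function(transcripts, upstream = 2000, downstream = 200,
                             contig_lengths = NULL) {
  data.table::rbindlist(lapply(transcripts, function(t) {
    w <- promoter_window(t, upstream, downstream,
                         contig_length = contig_lengths[[t$chrom]])
    data.table::data.table(gene_id = w$gene_id, transcript_id = w$transcript_id,
                           chrom = w$chrom, strand = w$strand,
                           start = w$start, end = w$end)
  }))
}
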