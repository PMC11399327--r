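# Downstream statistics on pipeline output: alternative-splicing event
# classification between isoforms, Wilcoxon differential isoform expression
# and differential accessibility at stated thresholds, peak-to-promoter
# annotation, and the splice-site / accessibility overlap fraction.

utils::globalVariables(c("i.start", "i.end", "peak_id", "overlap"))

.junction_set <- function(t) {
  ii <- transcript_introns(t)
  if (nrow(ii) == 0L) return(character(0))
  paste(ii[, 1L], ii[, 2L], sep = "-")
}

#' Classify alternative-splicing events between two isoforms
#'
#' Compares two isoforms of the same gene and returns the classified
#' differences. Event types (multiple may co-occur):
#'
#' * `AP` -- TSS differ by more than `tolerance_bp` (alternative promoter);
#'   site is the interval between the two TSS positions.
#' * `APA` -- TES differ (alternative polyadenylation); site analogous.
#' * `SE` -- an internal exon of one isoform is absent from the other while
#'   the flanking junctions are shared: `a` carries junctions `(x, e.start)`
#'   and `(e.end, y)` and `b` the single junction `(x, y)`; site is the
#'   skipped exon.
#' * `RI` -- one isoform's exon spans the other's intron with shared
#'   flanks; site is the retained intron.
#' * `MXE` -- two non-overlapping internal exons, each present in exactly
#'   one isoform, sharing outer flanking junction endpoints.
#' * `A3SS`/`A5SS` -- a junction sharing its donor (5' splice site) but not
#'   its acceptor is an alternative 3' splice site, and vice versa;
#'   strand-aware (on `+`, the donor is the intron start).
#'
#' @param a,b `TranscriptModel`s of the same gene and strand.
#' @param tolerance_bp End-difference tolerance for AP/APA (default 50).
#' @return data.table of events: `gene_id`, `event_type`, `chrom`,
#'   `site_start`, `site_end`, `transcript_a`, `transcript_b` (0 rows for
#'   identical feature sets).
#' @export
classify_as_events <- function(a, b, tolerance_bp = 50) {
  if (a$gene_id != b$gene_id) stop("isoforms belong to different genes")
  if (a$strand != b$strand) stop("isoforms on different strands")
  ev <- list()
  add <- function(type, s, e) {
    ev[[length(ev) + 1L]] <<- data.table::data.table(
      gene_id = a$gene_id, event_type = type, chrom = a$chrom,
      site_start = s, site_end = e,
      transcript_a = a$transcript_id, transcript_b = b$transcript_id)
  }
  if (abs(a$tss - b$tss) > tolerance_bp)
    add("AP", min(a$tss, b$tss), max(a$tss, b$tss))
  if (abs(a$tes - b$tes) > tolerance_bp)
    add("APA", min(a$tes, b$tes), max(a$tes, b$tes))

  ja <- transcript_introns(a); jb <- transcript_introns(b)
  key <- function(m) if (nrow(m)) paste(m[, 1L], m[, 2L], sep = "-") else character(0)
  ka <- key(ja); kb <- key(jb)

  # SE / MXE: internal exons of one absent from the other with shared flanks
  internal_exons <- function(t) {
    n <- nrow(t$exons)
    if (n < 3L) return(NULL)
    t$exons[2:(n - 1L), , drop = FALSE]
  }
  skipped <- function(x, jx, y, kx, ky) {
    # exons of x absent from y, with x's flanking junctions around the exon
    # replaced in y by the single spanning junction
    exi <- internal_exons(x)
    out <- NULL
    if (is.null(exi)) return(out)
    ye <- y$exons
    for (r in seq_len(nrow(exi))) {
      es <- exi[r, 1L]; ee <- exi[r, 2L]
      overlaps_y <- any(ye[, 1L] < ee & ye[, 2L] > es)
      if (overlaps_y) next
      left <- jx[jx[, 2L] == es, , drop = FALSE]
      right <- jx[jx[, 1L] == ee, , drop = FALSE]
      if (nrow(left) != 1L || nrow(right) != 1L) next
      span_key <- paste(left[1L, 1L], right[1L, 2L], sep = "-")
      out <- rbind(out, c(es, ee, x_flanks = span_key %in% ky,
                          lj = left[1L, 1L], rj = right[1L, 2L]))
    }
    out
  }
  sk_a <- skipped(a, ja, b, ka, kb)   # exons of a missing from b
  sk_b <- skipped(b, jb, a, kb, ka)
  if (!is.null(sk_a)) for (r in seq_len(nrow(sk_a)))
    if (sk_a[r, 3L] == 1) add("SE", sk_a[r, 1L], sk_a[r, 2L])
  if (!is.null(sk_b)) for (r in seq_len(nrow(sk_b)))
    if (sk_b[r, 3L] == 1) add("SE", sk_b[r, 1L], sk_b[r, 2L])
  # MXE: a-only exon and b-only exon, non-overlapping, sharing outer flanks
  if (!is.null(sk_a) && !is.null(sk_b)) {
    for (r in seq_len(nrow(sk_a))) for (q in seq_len(nrow(sk_b))) {
      e1 <- sk_a[r, ]; e2 <- sk_b[q, ]
      if (e1[1L] < e2[2L] && e1[2L] > e2[1L]) next  # overlapping
      if (e1[4L] == e2[4L] && e1[5L] == e2[5L]) {
        s <- min(e1[1L], e2[1L]); e <- max(e1[2L], e2[2L])
        add("MXE", s, e)
      }
    }
  }
  # RI: an exon of one spans an intron of the other whose flanks are shared
  ri_check <- function(x, y, jy) {
    if (nrow(jy) == 0L) return()
    for (k in seq_len(nrow(jy))) {
      s <- jy[k, 1L]; e <- jy[k, 2L]
      spanning <- x$exons[, 1L] < s & x$exons[, 2L] > e
      if (any(spanning) && !(paste(s, e, sep = "-") %in% key(transcript_introns(x))))
        add("RI", s, e)
    }
  }
  ri_check(a, b, jb)  # a retains an intron of b
  ri_check(b, a, ja)
  # A3SS / A5SS: junctions sharing one end only, where the two alternative
  # boundaries belong to overlapping exons of the two isoforms (i.e. the
  # same exon with a shifted splice site, not a different exon -- which
  # would be SE/MXE). Strand-aware naming: on "+" the intron start is the
  # donor (5' splice site) and the intron end the acceptor.
  if (nrow(ja) && nrow(jb)) {
    exon_from <- function(t, start_at) t$exons[t$exons[, 1L] == start_at, , drop = FALSE]
    exon_to <- function(t, end_at) t$exons[t$exons[, 2L] == end_at, , drop = FALSE]
    overlaps <- function(u, v) nrow(u) == 1L && nrow(v) == 1L &&
      u[1L, 1L] < v[1L, 2L] && u[1L, 2L] > v[1L, 1L]
    for (k in seq_len(nrow(ja))) {
      s1 <- ja[k, 1L]; e1 <- ja[k, 2L]
      if (paste(s1, e1, sep = "-") %in% kb) next
      shared_start <- jb[jb[, 1L] == s1 & jb[, 2L] != e1, , drop = FALSE]
      shared_end <- jb[jb[, 2L] == e1 & jb[, 1L] != s1, , drop = FALSE]
      for (q in seq_len(nrow(shared_start))) {
        e2 <- shared_start[q, 2L]
        if (!overlaps(exon_from(a, e1), exon_from(b, e2))) next
        type <- if (a$strand == "+") "A3SS" else "A5SS"
        add(type, min(e1, e2), max(e1, e2))
      }
      for (q in seq_len(nrow(shared_end))) {
        s2 <- shared_end[q, 1L]
        if (!overlaps(exon_to(a, s1), exon_to(b, s2))) next
        type <- if (a$strand == "+") "A5SS" else "A3SS"
        add(type, min(s1, s2), max(s1, s2))
      }
    }
  }
  if (length(ev) == 0L)
    return(data.table::data.table(gene_id = character(), event_type = character(),
                                  chrom = character(), site_start = numeric(),
                                  site_end = numeric(), transcript_a = character(),
                                  transcript_b = character()))
  unique(data.table::rbindlist(ev))
}

# counts-per-10k + log1p normalization per cell
.normalize_cp10k <- function(counts) {
  cs <- Matrix::colSums(counts)
  cs[cs == 0] <- 1
  log1p(t(t(as.matrix(counts)) / cs * 1e4))
}

.wilcox_table <- function(norm, groups, lfc_pseudo = 1) {
  g1 <- names(groups)[groups == levels(factor(groups))[1L]]
  g2 <- names(groups)[groups == levels(factor(groups))[2L]]
  lin <- expm1(norm)
  res <- data.table::rbindlist(lapply(rownames(norm), function(f) {
    x <- norm[f, g1]; y <- norm[f, g2]
    p <- if (stats::sd(c(x, y)) == 0) 1
         else suppressWarnings(stats::wilcox.test(x, y)$p.value)
    m1 <- mean(lin[f, g1]); m2 <- mean(lin[f, g2])
    data.table::data.table(feature_id = f,
                           mean_group1 = m1, mean_group2 = m2,
                           log2_fold_change = log2((m1 + lfc_pseudo) /
                                                   (m2 + lfc_pseudo)),
                           p_value = p)
  }))
  res$adjusted_p <- stats::p.adjust(res$p_value, method = "BH")
  res
}

#' Differential isoform expression between two cell groups
#'
#' Two-sided Wilcoxon rank-sum test per isoform on counts-per-10k
#' log-normalized values, Benjamini-Hochberg adjustment; an isoform is
#' significant when `|log2FC| > 0.25` and adjusted p < 0.05. When
#' `features` supplies a gene map, the isoform-switch columns are added:
#' the change in within-gene isoform fraction `dIF`, flagged at
#' `|dIF| > 0.1` with adjusted p < `alpha` (0.05).
#'
#' @param matrix `IsoformCountMatrix` or count matrix (isoforms x cells).
#' @param groups Named character/factor: cell barcode -> group label
#'   (exactly two groups, >= 3 cells each).
#' @param lfc_cutoff,p_cutoff Significance thresholds (defaults 0.25 and
#'   0.05 on the adjusted p).
#' @param features Optional data.table `transcript_id` -> `gene_id`
#'   enabling the isoform-switch variant.
#' @param alpha,dif_cutoff Switch-test thresholds (defaults 0.05, 0.1).
#' @return `DiffTable` data.table: `feature_id`, group means,
#'   `log2_fold_change`, `p_value`, `adjusted_p`, `significant` (and `dIF`,
#'   `switch_significant` when `features` given).
#' @export
differential_isoforms <- function(matrix, groups, lfc_cutoff = 0.25,
                                  p_cutoff = 0.05, features = NULL,
                                  alpha = 0.05, dif_cutoff = 0.1) {
  counts <- .counts_of(matrix)
  groups <- groups[!is.na(groups)]
  lv <- unique(groups)
  if (length(lv) != 2L) stop("need exactly two groups")
  if (any(table(groups) < 3L)) stop("each group needs >= 3 cells")
  counts <- counts[, names(groups), drop = FALSE]
  norm <- .normalize_cp10k(counts)
  res <- .wilcox_table(norm, groups)
  res$significant <- abs(res$log2_fold_change) > lfc_cutoff &
    res$adjusted_p < p_cutoff
  if (!is.null(features)) {
    gene <- features$gene_id[match(res$feature_id, features$transcript_id)]
    raw <- as.matrix(counts)
    if1 <- .isoform_fraction(raw[, names(groups)[groups == lv[1L]], drop = FALSE], gene)
    if2 <- .isoform_fraction(raw[, names(groups)[groups == lv[2L]], drop = FALSE], gene)
    res$dIF <- if1 - if2
    res$switch_significant <- abs(res$dIF) > dif_cutoff & res$adjusted_p < alpha
  }
  res
}

# within-gene isoform fraction of summed counts
.isoform_fraction <- function(counts, gene) {
  tot <- rowSums(counts)
  gt <- tapply(tot, gene, sum)[gene]
  ifr <- ifelse(gt > 0, tot / gt, 0)
  as.numeric(ifr)
}

#' Differential accessibility of peaks between two cell groups
#'
#' Same Wilcoxon machinery as [differential_isoforms()] with the
#' accessibility thresholds: significant when `|log2FC| > 0.1` and raw
#' p < 0.0005 (unadjusted).
#'
#' @param peaks Peak-by-cell count matrix (rownames are peak ids) or a
#'   data.table with `chrom`, `start`, `end` plus one column per cell.
#' @param groups Named vector: cell -> group (two groups, >= 3 cells each).
#' @param lfc_cutoff,p_cutoff Thresholds (defaults 0.1 and 0.0005).
#' @return `DiffTable` with `significant` flag on the raw p-value.
#' @export
differential_peaks <- function(peaks, groups, lfc_cutoff = 0.1,
                               p_cutoff = 5e-4) {
  if (is.data.frame(peaks)) {
    pk <- data.table::as.data.table(peaks)
    ids <- sprintf("%s:%d-%d", pk$chrom, as.integer(pk$start), as.integer(pk$end))
    counts <- as.matrix(pk[, !c("chrom", "start", "end")])
    rownames(counts) <- ids
  } else counts <- as.matrix(peaks)
  if (any(counts < 0)) stop("negative accessibility counts")
  groups <- groups[!is.na(groups)]
  if (length(unique(groups)) != 2L) stop("need exactly two groups")
  if (any(table(groups) < 3L)) stop("each group needs >= 3 cells")
  counts <- counts[, names(groups), drop = FALSE]
  norm <- .normalize_cp10k(counts)
  res <- .wilcox_table(norm, groups)
  res$significant <- abs(res$log2_fold_change) > lfc_cutoff &
    res$p_value < p_cutoff
  res
}

#' Annotate peaks to promoters or nearest genes
#'
#' A peak overlapping any promoter window (TSS -2000/+200, strand-aware)
#' is annotated `"promoter"` of that gene; otherwise it is assigned to the
#' nearest gene span with a signed genomic distance (negative when the peak
#' lies left of the gene). Ties break to the smaller gene id.
#'
#' @param peaks data.table with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param transcripts List of `TranscriptModel`.
#' @return data.table: peak columns plus `gene_id`, `annotation`
#'   (`"promoter"`/`"distal"`), `distance` (0 for promoter/overlap).
#' @export
annotate_peaks_to_promoters <- function(peaks, transcripts) {
  pk <- data.table::as.data.table(peaks)
  pw <- promoter_windows(transcripts)
  genes <- data.table::rbindlist(lapply(transcripts, function(t)
    data.table::data.table(gene_id = t$gene_id, chrom = t$chrom,
                           gstart = t$exons[1L, 1L],
                           gend = t$exons[nrow(t$exons), 2L])))
  genes <- genes[, list(gstart = min(gstart), gend = max(gend)),
                 by = c("gene_id", "chrom")]
  out <- lapply(seq_len(nrow(pk)), function(i) {
    ch <- pk$chrom[i]; s <- pk$start[i]; e <- pk$end[i]
    hit <- pw[pw$chrom == ch & pw$start < e & pw$end > s]
    if (nrow(hit))
      return(data.table::data.table(gene_id = sort(unique(hit$gene_id))[1L],
                                    annotation = "promoter", distance = 0))
    g <- genes[genes$chrom == ch]
    if (nrow(g) == 0L)
      return(data.table::data.table(gene_id = NA_character_,
                                    annotation = "unplaced", distance = NA_real_))
    d <- ifelse(g$gstart >= e, g$gstart - e,        # peak left of gene
         ifelse(g$gend <= s, -(s - g$gend), 0))     # peak right -> negative
    # distance sign: positive when the peak lies upstream-left; magnitude is
    # the gap. Nearest by |d|, ties to smaller gene_id.
    ord <- order(abs(d), g$gene_id)
    data.table::data.table(gene_id = g$gene_id[ord[1L]],
                           annotation = if (abs(d[ord[1L]]) == 0) "gene_body" else "distal",
                           distance = -d[ord[1L]])
  })
  cbind(pk, data.table::rbindlist(out))
}

#' Fraction of splicing sites overlapping differentially accessible regions
#'
#' For each alternative-splicing event, tests whether any significant
#' differentially accessible region (DAR) overlaps the window
#' `[site - window_bp, site + window_bp)` around the event site. Returns
#' the overlapping fraction over all events, the SE-only fraction, and
#' per-event flags.
#'
#' @param events data.table of AS events (see [classify_as_events()]).
#' @param dars data.table of significant peaks: `chrom`, `start`, `end`.
#' @param window_bp Half-width of the window (default 100).
#' @return List: `fraction` (all events), `fraction_se` (SE events only;
#'   `NA` if none), `n_events`, `n_overlapping`, `events` (with `overlap`
#'   flag).
#' @export
splice_site_dar_overlap <- function(events, dars, window_bp = 100) {
  ev <- data.table::as.data.table(events)
  if (nrow(ev) == 0L) stop("empty event list")
  da <- data.table::as.data.table(dars)
  ov <- vapply(seq_len(nrow(ev)), function(i) {
    ws <- ev$site_start[i] - window_bp; we <- ev$site_end[i] + window_bp
    nrow(da) > 0L && any(da$chrom == ev$chrom[i] & da$start < we & da$end > ws)
  }, TRUE)
  ev$overlap <- ov
  se <- ev$event_type == "SE"
  list(fraction = mean(ov),
       fraction_se = if (any(se)) mean(ov[se]) else NA_real_,
       n_events = nrow(ev), n_overlapping = sum(ov), events = ev)
}

#' Export splice-site windows as BED
#'
#' Writes the `[site - window_bp, site + window_bp)` windows of AS events
#' in BED format for external motif tools.
#'
#' @param events data.table of AS events.
#' @param path Output BED path.
#' @param window_bp Half-width (default 100).
#' @return `path`, invisibly.
#' @export
as_site_windows <- function(events, path, window_bp = 100) {
  ev <- data.table::as.data.table(events)
  gr <- GenomicRanges::GRanges(
    seqnames = ev$chrom,
    ranges = IRanges::IRanges(start = pmax(ev$site_start - window_bp, 0) + 1L,
                              end = ev$site_end + window_bp),
    name = paste(ev$gene_id, ev$event_type, sep = "_"))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
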