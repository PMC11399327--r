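# alternative-splicing classification, differential tests, peak annotation

# independent event oracle: naive loops over exon/junction sets
oracle_events <- function(a, b, tol = 50) {
  ev <- character(0)
  introns <- function(t) {
    n <- nrow(t$exons)
    if (n < 2) return(matrix(numeric(0), ncol = 2))
    cbind(t$exons[-n, 2], t$exons[-1, 1])
  }
  ja <- introns(a); jb <- introns(b)
  jk <- function(m) if (nrow(m)) paste(m[, 1], m[, 2]) else character(0)
  if (abs(a$tss - b$tss) > tol) ev <- c(ev, "AP")
  if (abs(a$tes - b$tes) > tol) ev <- c(ev, "APA")
  skipped_of <- function(x, y) {
    jx <- introns(x); out <- NULL
    if (nrow(x$exons) < 3) return(out)
    for (r in 2:(nrow(x$exons) - 1)) {
      es <- x$exons[r, 1]; ee <- x$exons[r, 2]
      if (any(y$exons[, 1] < ee & y$exons[, 2] > es)) next
      l <- jx[jx[, 2] == es, , drop = FALSE]
      rr <- jx[jx[, 1] == ee, , drop = FALSE]
      if (nrow(l) == 1 && nrow(rr) == 1)
        out <- rbind(out, c(es, ee, l[1, 1], rr[1, 2]))
    }
    out
  }
  sa <- skipped_of(a, b); sb <- skipped_of(b, a)
  if (!is.null(sa)) for (r in seq_len(nrow(sa)))
    if (paste(sa[r, 3], sa[r, 4]) %in% jk(jb)) ev <- c(ev, "SE")
  if (!is.null(sb)) for (r in seq_len(nrow(sb)))
    if (paste(sb[r, 3], sb[r, 4]) %in% jk(ja)) ev <- c(ev, "SE")
  if (!is.null(sa) && !is.null(sb))
    for (r in seq_len(nrow(sa))) for (q in seq_len(nrow(sb)))
      if ((sa[r, 1] >= sb[q, 2] || sa[r, 2] <= sb[q, 1]) &&
          sa[r, 3] == sb[q, 3] && sa[r, 4] == sb[q, 4]) ev <- c(ev, "MXE")
  ri_of <- function(x, jy, jx) {
    n <- 0
    for (k in seq_len(nrow(jy)))
      if (any(x$exons[, 1] < jy[k, 1] & x$exons[, 2] > jy[k, 2]) &&
          !(paste(jy[k, 1], jy[k, 2]) %in% jk(jx))) n <- n + 1
    n
  }
  ev <- c(ev, rep("RI", ri_of(a, jb, ja) + ri_of(b, ja, jb)))
  if (nrow(ja) && nrow(jb)) {
    for (k in seq_len(nrow(ja))) for (q in seq_len(nrow(jb))) {
      j1 <- ja[k, ]; j2 <- jb[q, ]
      if (all(j1 == j2)) next
      if (j1[1] == j2[1] && j1[2] != j2[2]) {
        ea <- a$exons[a$exons[, 1] == j1[2], , drop = FALSE]
        eb <- b$exons[b$exons[, 1] == j2[2], , drop = FALSE]
        if (nrow(ea) == 1 && nrow(eb) == 1 &&
            ea[1, 1] < eb[1, 2] && ea[1, 2] > eb[1, 1])
          ev <- c(ev, if (a$strand == "+") "A3SS" else "A5SS")
      }
      if (j1[2] == j2[2] && j1[1] != j2[1]) {
        ea <- a$exons[a$exons[, 2] == j1[1], , drop = FALSE]
        eb <- b$exons[b$exons[, 2] == j2[1], , drop = FALSE]
        if (nrow(ea) == 1 && nrow(eb) == 1 &&
            ea[1, 1] < eb[1, 2] && ea[1, 2] > eb[1, 1])
          ev <- c(ev, if (a$strand == "+") "A5SS" else "A3SS")
      }
    }
  }
  sort(ev)
}

test_that("rule-forced classifications: SE, RI, MXE, A3SS/A5SS, AP/APA", {
  a <- transcript_model("A", "g", "c", "+",
                        rbind(c(100, 200), c(300, 400), c(500, 600)))
  b <- transcript_model("B", "g", "c", "+", rbind(c(100, 200), c(500, 600)))
  se <- classify_as_events(a, b)
  expect_equal(se$event_type, "SE")
  expect_equal(c(se$site_start, se$site_end), c(300, 400))
  ri <- classify_as_events(transcript_model("R", "g", "c", "+",
                                            rbind(c(100, 600))), b)
  expect_equal(ri$event_type, "RI")
  expect_equal(c(ri$site_start, ri$site_end), c(200, 500))
  m1 <- transcript_model("M1", "g", "c", "+",
                         rbind(c(100, 200), c(300, 400), c(700, 800)))
  m2 <- transcript_model("M2", "g", "c", "+",
                         rbind(c(100, 200), c(500, 600), c(700, 800)))
  expect_equal(classify_as_events(m1, m2)$event_type, "MXE")
  b2 <- transcript_model("B2", "g", "c", "+", rbind(c(100, 200), c(450, 600)))
  expect_equal(classify_as_events(b, b2)$event_type, "A3SS")
  # minus strand flips the alternative splice-site polarity
  bm <- transcript_model("Bm", "g", "c", "-", rbind(c(100, 200), c(500, 600)))
  bm2 <- transcript_model("Bm2", "g", "c", "-", rbind(c(100, 200), c(450, 600)))
  expect_equal(classify_as_events(bm, bm2)$event_type, "A5SS")
  p2 <- transcript_model("P2", "g", "c", "+", rbind(c(300, 900)))
  ap <- classify_as_events(transcript_model("P1", "g", "c", "+",
                                            rbind(c(100, 600))), p2)
  expect_setequal(ap$event_type, c("AP", "APA"))
  # identical feature sets -> no events; different genes -> error
  expect_equal(nrow(classify_as_events(
    a, transcript_model("A2", "g", "c", "+", a$exons))), 0L)
  expect_error(classify_as_events(
    a, transcript_model("X", "other", "c", "+", a$exons)), "different genes")
})

test_that("classification agrees with the exon-set oracle on synthetic pairs", {
  n_checked <- 0L
  for (seed in c(7, 19)) {
    ann <- make_synthetic_annotation(n_isoforms = 16, n_genes = 2, n_ercc = 0,
                                     seed = seed)
    tx <- ann$transcripts
    genes <- split(names(tx), vapply(tx, `[[`, "", "gene_id"))
    for (g in genes) {
      prs <- utils::combn(g, 2)
      for (k in seq_len(ncol(prs))) {
        a <- tx[[prs[1, k]]]; b <- tx[[prs[2, k]]]
        got <- sort(classify_as_events(a, b)$event_type)
        expect_identical(got, oracle_events(a, b),
                         info = paste(a$transcript_id, b$transcript_id, seed))
        n_checked <- n_checked + 1L
      }
    }
  }
  expect_gte(n_checked, 100L)
})

test_that("classification is symmetric in its arguments up to polarity", {
  ann <- make_synthetic_annotation(n_isoforms = 8, n_genes = 1, n_ercc = 0,
                                   seed = 13)
  tx <- ann$transcripts
  prs <- utils::combn(names(tx), 2)
  for (k in seq_len(ncol(prs))) {
    ab <- classify_as_events(tx[[prs[1, k]]], tx[[prs[2, k]]])
    ba <- classify_as_events(tx[[prs[2, k]]], tx[[prs[1, k]]])
    expect_identical(sort(ab$event_type), sort(ba$event_type))
    expect_identical(ab[order(site_start, site_end, event_type),
                        c("event_type", "site_start", "site_end")],
                     ba[order(site_start, site_end, event_type),
                        c("event_type", "site_start", "site_end")])
  }
})

make_null_matrix <- function(n_iso, n_cells, seed) {
  set.seed(seed)
  matrix(rpois(n_iso * n_cells, 5), nrow = n_iso,
         dimnames = list(sprintf("iso%03d", seq_len(n_iso)),
                         sprintf("cell%02d", seq_len(n_cells))))
}

test_that("Wilcoxon null: permuted labels keep type-I error within bounds", {
  cts <- make_null_matrix(40, 30, 202)
  set.seed(203)
  frac <- vapply(1:100, function(i) {
    g <- setNames(sample(rep(c("g1", "g2"), c(15, 15))), colnames(cts))
    d <- differential_isoforms(cts, g)
    mean(d$significant)
  }, 0)
  expect_lte(mean(frac), 0.05)
})

test_that("significance flags flip at the stated isoform thresholds", {
  # column totals fixed at 1e4 so cp10k-normalized values equal raw counts
  mk <- function(a1, a2, n = 20) {
    x <- rbind(c(rep(a1, n), rep(a2, n)),
               c(rep(1e4 - a1, n), rep(1e4 - a2, n)))
    dimnames(x) <- list(c("X", "filler"), sprintf("c%02d", seq_len(2 * n)))
    x
  }
  g <- setNames(rep(c("g1", "g2"), each = 20), sprintf("c%02d", 1:40))
  # log2(121/100) = 0.275 > 0.25 -> significant
  d_hi <- differential_isoforms(mk(120, 99), g)
  expect_true(d_hi[d_hi$feature_id == "X"]$significant)
  # log2(116/100) = 0.214 < 0.25 -> not significant despite tiny p
  d_lo <- differential_isoforms(mk(115, 99), g)
  expect_false(d_lo[d_lo$feature_id == "X"]$significant)
  expect_lt(d_lo[d_lo$feature_id == "X"]$p_value, 1e-6)
  expect_error(differential_isoforms(mk(120, 99), g[c(1:2, 21:22)]),
               ">= 3 cells")
})

test_that("isoform-switch variant flags |dIF| > 0.1 at alpha 0.05", {
  n <- 20
  cts <- rbind(c(rep(600, n), rep(400, n)),
               c(rep(400, n), rep(600, n)))
  dimnames(cts) <- list(c("T1", "T2"), sprintf("c%02d", seq_len(2 * n)))
  g <- setNames(rep(c("g1", "g2"), each = n), colnames(cts))
  feats <- data.table::data.table(transcript_id = c("T1", "T2"), gene_id = "G")
  d <- differential_isoforms(cts, g, features = feats)
  expect_equal(d[d$feature_id == "T1"]$dIF, 0.2, tolerance = 1e-9)
  expect_true(all(d$switch_significant))
})

test_that("peak thresholds: |log2FC| > 0.1 with raw p < 0.0005", {
  mk <- function(a1, a2, n = 10) {
    x <- rbind(c(rep(a1, n), rep(a2, n)),
               c(rep(1e4 - a1, n), rep(1e4 - a2, n)))
    dimnames(x) <- list(c("P", "filler"), sprintf("c%02d", seq_len(2 * n)))
    x
  }
  g <- setNames(rep(c("g1", "g2"), each = 10), sprintf("c%02d", 1:20))
  d_hi <- differential_peaks(mk(110, 99), g)   # log2(111/100) = 0.151
  expect_true(d_hi[d_hi$feature_id == "P"]$significant)
  d_lo <- differential_peaks(mk(105, 99), g)   # log2(106/100) = 0.084
  expect_false(d_lo[d_lo$feature_id == "P"]$significant)
  # null permutation of a homogeneous population -> nothing significant
  cts <- make_null_matrix(30, 20, 205)
  set.seed(206)
  gg <- setNames(sample(rep(c("g1", "g2"), c(10, 10))), colnames(cts))
  expect_equal(sum(differential_peaks(cts, gg)$significant), 0L)
})

test_that("peak annotation matches a brute-force distance scan", {
  set.seed(301)
  tx <- lapply(1:12, function(i) {
    s <- sample(5000:200000, 1)
    transcript_model(sprintf("t%02d", i), sprintf("g%02d", i),
                     sample(c("c1", "c2"), 1), sample(c("+", "-"), 1),
                     rbind(c(s, s + 2000)))
  })
  names(tx) <- vapply(tx, `[[`, "", "transcript_id")
  peaks <- data.table::data.table(
    chrom = sample(c("c1", "c2"), 60, replace = TRUE),
    start = sample(1:250000, 60))
  peaks$end <- peaks$start + 500
  got <- annotate_peaks_to_promoters(peaks, tx)
  pw <- promoter_windows(tx)
  for (i in seq_len(nrow(peaks))) {
    hits <- pw[pw$chrom == peaks$chrom[i] & pw$start < peaks$end[i] &
                 pw$end > peaks$start[i]]
    if (nrow(hits)) {
      expect_identical(got$annotation[i], "promoter")
      expect_identical(got$gene_id[i], sort(unique(hits$gene_id))[1])
    } else {
      cand <- Filter(function(t) t$chrom == peaks$chrom[i], tx)
      d <- vapply(cand, function(t) {
        gs <- t$exons[1, 1]; ge <- t$exons[nrow(t$exons), 2]
        if (gs >= peaks$end[i]) gs - peaks$end[i]
        else if (ge <= peaks$start[i]) peaks$start[i] - ge
        else 0
      }, 0)
      best <- names(cand)[order(d, vapply(cand, `[[`, "", "gene_id"))[1]]
      expect_identical(got$gene_id[i], cand[[best]]$gene_id)
      expect_equal(abs(got$distance[i]), unname(min(d)))
    }
  }
})

test_that("splice-site / DAR overlap fraction and monotonicity", {
  events <- data.table::data.table(
    gene_id = "g", event_type = rep(c("SE", "RI"), 5000),
    chrom = "c1", site_start = (1:10000) * 1000,
    site_end = (1:10000) * 1000 + 100)
  no_dar <- data.table::data.table(chrom = character(), start = numeric(),
                                   end = numeric())
  expect_equal(splice_site_dar_overlap(events, no_dar)$fraction, 0)
  all_dar <- data.table::data.table(chrom = "c1", start = 0, end = 2e7)
  expect_equal(splice_site_dar_overlap(events, all_dar)$fraction, 1)
  # 743 of 10000 sites covered -> 0.0743
  dar743 <- data.table::data.table(chrom = "c1", start = 900,
                                   end = 743 * 1000 + 150)
  ov <- splice_site_dar_overlap(events, dar743)
  expect_equal(ov$fraction, 0.0743)
  expect_equal(ov$n_overlapping, 743L)
  # per-SE denominator is also reported
  expect_equal(ov$fraction_se, mean(ov$events$overlap[
    ov$events$event_type == "SE"]))
  # monotone non-decreasing in window_bp
  far_dar <- data.table::data.table(chrom = "c1", start = 1500, end = 1600)
  fr <- vapply(c(0, 100, 300, 500), function(w)
    splice_site_dar_overlap(events, far_dar, window_bp = w)$fraction, 0)
  expect_true(all(diff(fr) >= 0))
  expect_error(splice_site_dar_overlap(events[0], all_dar), "empty")
})

test_that("AS site windows export as BED", {
  ev <- data.table::data.table(gene_id = "g", event_type = "SE", chrom = "c1",
                               site_start = 5000, site_end = 5200)
  bed <- tempfile(fileext = ".bed")
  as_site_windows(ev, bed)
  l <- read.table(bed, sep = "\t")
  expect_equal(l$V2, 4900)  # BED is 0-based half-open
  expect_equal(l$V3, 5300)
})
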