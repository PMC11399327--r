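# UMI grouping, feature matching, direct + probabilistic assignment

test_that("fragments group by (cb, gene, umi) and unassigned genes drop", {
  f <- data.table::data.table(
    frag_id = 1:6,
    read_id = paste0("r", 1:6),
    cb = c("AA", "AA", "AA", "AA", "CC", "CC"),
    umi = c("U1", "U1", "U1", "U1", "U2", "U2"),
    gene_id = c("g1", "g1", "g2", NA, "g1", "g1;g2"),
    end_class = c("TSS", "TES", "TSS", "TSS", "TSS", "TES"),
    chrom = "c", strand = "+")
  gu <- group_umis(f)
  expect_equal(nrow(gu$groups), 3L)  # same (cb,umi) two genes -> two groups
  expect_equal(unname(gu$dropped), c(1L, 1L))
  both <- gu$groups[gu$groups$cb == "AA" & gu$groups$gene_id == "g1"]
  expect_identical(both$end_classes_present, "TSS,TES")
  # conservation: kept fragments + dropped = input
  expect_equal(nrow(gu$fragments) + sum(gu$dropped), nrow(f))
})

test_that("match_features resolves ends, junctions and intron spans", {
  tx <- list(
    A = transcript_model("A", "g", "c", "+", rbind(c(100, 400), c(700, 1000))),
    B = transcript_model("B", "g", "c", "+", rbind(c(500, 520), c(700, 1000))),
    C = transcript_model("C", "g", "c", "+", rbind(c(300, 1000))))
  idx <- build_feature_index(tx, tolerance_bp = 50)
  # TSS terminus at 105: only A's TSS within 50
  g1 <- list(gene_id = "g", fragments = list(
    list(end_class = "TSS", blocks = cbind(105, 195))))
  expect_identical(match_features(g1, idx)$compat, "A")
  # junction unique to B (5' terminus also within tolerance of B's TSS)
  g2 <- list(gene_id = "g", fragments = list(
    list(end_class = "TSS", blocks = rbind(c(505, 520), c(700, 760)))))
  expect_identical(match_features(g2, idx)$compat, "B")
  # contiguous block across A's and B's introns excludes both, keeps C
  # (3' terminus matches the shared TES of all three)
  g3 <- list(gene_id = "g", fragments = list(
    list(end_class = "TES", blocks = cbind(300, 1000))))
  expect_identical(match_features(g3, idx)$compat, "C")
  # unknown gene
  expect_identical(match_features(list(gene_id = "nope", fragments = list()),
                                  idx)$reason, "gene_not_indexed")
})

test_that("match_features equals the brute-force oracle on random groups", {
  for (seed in c(81, 82)) {
    ann <- random_annotation(seed)
    idx <- build_feature_index(ann$transcripts, tolerance_bp = 50)
    mol <- simulate_molecules(ann, n_cells = 2, depth_scale = 0.4,
                              seed = seed + 1)
    al <- emit_alignments(mol, ann)
    res <- run_pipeline(al$tss_sam, al$tes_sam, idx)
    # rebuild groups and compare all three routes
    a1 <- read_tagged_alignments(al$tss_sam, "TSS")
    a2 <- read_tagged_alignments(al$tes_sam, "TES")
    a2$fragments[, frag_id := frag_id + nrow(a1$fragments)]
    a2$blocks[, frag_id := frag_id + nrow(a1$fragments)]
    f <- rbind(a1$fragments, a2$fragments)
    b <- rbind(a1$blocks, a2$blocks)
    gu <- group_umis(f)
    f2 <- gu$fragments
    vec <- pairiso:::match_features_all(f2, b[f2[, c("frag_id", "gid")],
                                              on = "frag_id", nomatch = 0L][
                                          , c("frag_id", "bstart", "bend")],
                                        idx)
    sets_vec <- split(vec$compat$transcript_id, vec$compat$gid)
    gids <- sample(unique(f2$gid), 60)
    for (gid_ in gids) {
      sub <- f2[f2$gid == gid_]
      frs <- lapply(sub$frag_id, function(fid) {
        bb <- b[b$frag_id == fid]
        list(end_class = sub$end_class[sub$frag_id == fid],
             blocks = cbind(bb$bstart, bb$bend))
      })
      expected <- brute_compat(ann$transcripts, sub$gene_id[1], frs, 50)
      expect_identical(match_features(list(gene_id = sub$gene_id[1],
                                           fragments = frs), idx)$compat,
                       expected)
      got_vec <- sort(sets_vec[[as.character(gid_)]])
      if (is.null(got_vec)) got_vec <- character(0)
      expect_identical(got_vec, expected)
    }
  }
})

test_that("assign_direct splits by compatibility-set size", {
  expect_identical(assign_direct("A")$method, "direct")
  amb <- assign_direct(c("B", "A"))
  expect_identical(amb$method, "ambiguous")
  expect_identical(amb$transcript_id, c("A", "B"))
  un <- assign_direct(character(0))
  expect_identical(un$method, "unassigned")
  expect_identical(un$reason, "no_compatible")
})

test_that("probabilistic rescue is abundance arg-max with lexicographic ties", {
  amb <- list(list(transcript_id = c("A", "B")))
  got <- assign_probabilistic(amb, c(A = 9, B = 1))[[1]]
  expect_identical(got$transcript_id, "A")
  expect_identical(got$method, "probabilistic")
  expect_equal(got$probability, 10 / 12)
  # zero direct counts: pseudocount only -> lexicographic tie-break
  expect_identical(assign_probabilistic(amb, numeric(0))[[1]]$transcript_id, "A")
})

test_that("rescue assigns >= 80% of end-ambiguous UMIs to the generating isoform", {
  # two isoforms sharing ends, differing by a cassette exon; 90/10 mix
  tx <- list(
    ISOA = transcript_model("ISOA", "g", "c", "+",
                            rbind(c(100, 400), c(600, 700), c(900, 1200))),
    ISOB = transcript_model("ISOB", "g", "c", "+",
                            rbind(c(100, 400), c(900, 1200))))
  genome <- stats::setNames(paste(rep("ACGTG", 400), collapse = ""), "c")
  truth <- data.table::data.table(
    species_id = c("ISOA", "ISOB"), transcript_id = c("ISOA", "ISOB"),
    gene_id = "g", class = "sirv", expected_abundance = c(90, 10))
  ann <- structure(list(transcripts = tx, genome = genome, truth = truth),
                   class = "synthetic_annotation")
  set.seed(1)
  mol <- simulate_molecules(ann, n_cells = 4, depth_scale = 1, seed = 101)
  n <- nrow(mol)
  full_idx <- seq_len(n) %% 5 != 0   # ~20% of UMIs end-ambiguous
  d1 <- emit_alignments(mol[full_idx], ann, tile = "all",
                        out_dir = tempfile())
  d2 <- emit_alignments(mol[!full_idx], ann, tile = "none",
                        out_dir = tempfile())
  tss <- combine_sams(tempfile(fileext = ".sam"), d1$tss_sam, d2$tss_sam)
  tes <- combine_sams(tempfile(fileext = ".sam"), d1$tes_sam, d2$tes_sam)
  res <- run_pipeline(tss, tes, tx)
  expect_gt(res$report$assigned_probabilistic, 0L)
  resc <- res$assignments[res$assignments$method == "probabilistic"]
  m <- merge(resc, mol, by = c("cb", "umi"))
  expect_gte(mean(m$transcript_id.x == m$transcript_id.y), 0.80)
  # conservation: groups = direct + probabilistic + unassigned (+ leftovers)
  r <- res$report
  expect_equal(r$n_groups, r$assigned_direct + r$assigned_probabilistic +
                 r$unassigned + r$ambiguous_remaining)
})

test_that("build_matrix counts per (transcript, cell) with provenance", {
  a <- data.table::data.table(
    cb = c("c1", "c1", "c1", "c2"),
    transcript_id = c("A", "A", "A", "B"),
    method = c("direct", "direct", "direct", "probabilistic"))
  m <- build_matrix(a)
  expect_equal(m$counts["A", "c1"], 3)
  expect_equal(m$direct["A", "c1"], 3)
  expect_equal(m$probabilistic["B", "c2"], 1)
  expect_equal(as.numeric(Matrix::colSums(m$counts)), c(3, 1))
  e <- build_matrix(a[0])
  expect_equal(sum(e$counts), 0)
  expect_equal(unname(e$summary["assigned"]), 0L)
})

test_that("noise-free end-to-end run is 100% direct and matches ground truth", {
  ann <- random_annotation(91)
  mol <- simulate_molecules(ann, n_cells = 3, depth_scale = 0.6, seed = 92)
  al <- emit_alignments(mol, ann)
  res <- run_pipeline(al$tss_sam, al$tes_sam, ann$transcripts)
  expect_equal(res$report$assigned_direct, res$report$n_groups)
  idx <- res$index
  acc <- feature_accuracy(res$assignments, mol, idx$indistinguishable)
  expect_equal(as.numeric(acc), 1.0)
  # column sums equal per-cell assigned-UMI totals
  percell <- table(res$assignments$cb)
  expect_equal(as.numeric(Matrix::colSums(res$matrix$counts)[names(percell)]),
               as.numeric(percell))
})

test_that("the pipeline is invariant to input record order", {
  ann <- random_annotation(95)
  mol <- simulate_molecules(ann, n_cells = 2, depth_scale = 0.3, seed = 96)
  al <- emit_alignments(mol, ann)
  shuffle <- function(p) {
    l <- readLines(p)
    hdr <- l[startsWith(l, "@")]; body <- l[!startsWith(l, "@")]
    set.seed(4); out <- tempfile(fileext = ".sam")
    writeLines(c(hdr, sample(body)), out)
    out
  }
  r1 <- run_pipeline(al$tss_sam, al$tes_sam, ann$transcripts)
  r2 <- run_pipeline(shuffle(al$tss_sam), shuffle(al$tes_sam), ann$transcripts)
  expect_identical(as.matrix(r1$matrix$counts), as.matrix(r2$matrix$counts))
  expect_identical(r1$report$assigned_direct, r2$report$assigned_direct)
})

test_that("empty inputs yield an empty matrix", {
  ann <- random_annotation(97)
  sam <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6", sprintf("@SQ\tSN:%s\tLN:%d",
                                      names(ann$genome), nchar(ann$genome))),
             sam)
  res <- run_pipeline(sam, sam, ann$transcripts)
  expect_equal(res$report$n_groups, 0L)
  expect_equal(sum(res$matrix$counts), 0)
})
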