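# Fixtures are built in code; nothing is read from disk except files the
# helpers themselves write to tempdir().

# two-gene toy annotation exercising both strands and all feature kinds
toy_transcripts <- function() {
  list(
    # gene gA (+): A1 full, A2 skips the middle exon, A3 alternative TSS
    A1 = transcript_model("A1", "gA", "chrT", "+",
                          rbind(c(100, 400), c(700, 900), c(1200, 1500))),
    A2 = transcript_model("A2", "gA", "chrT", "+",
                          rbind(c(100, 400), c(1200, 1500))),
    A3 = transcript_model("A3", "gA", "chrT", "+",
                          rbind(c(250, 400), c(700, 900), c(1200, 1500))),
    # gene gB (-): alternative TES (B2) on the minus strand
    B1 = transcript_model("B1", "gB", "chrU", "-",
                          rbind(c(2000, 2300), c(2600, 2900))),
    B2 = transcript_model("B2", "gB", "chrU", "-",
                          rbind(c(2150, 2300), c(2600, 2900))))
}

# random multi-isoform annotation for property tests (small, fast)
random_annotation <- function(seed) {
  make_synthetic_annotation(n_isoforms = 12, n_genes = 3, n_ercc = 8,
                            seed = seed)
}

# brute-force end-query oracle straight from the TranscriptModel list
brute_query_end <- function(transcripts, gene_id, pos, end_class, tol) {
  hits <- vapply(transcripts, function(t) {
    t$gene_id == gene_id &&
      abs((if (end_class == "TSS") t$tss else t$tes) - pos) <= tol
  }, TRUE)
  sort(names(transcripts)[hits])
}

# brute-force UMI-group compatibility oracle: per-transcript test straight
# from exon structures (independent of FeatureIndex internals)
brute_compat <- function(transcripts, gene_id, frags, tol) {
  # frags: list of list(end_class, blocks)
  strand <- NULL
  for (t in transcripts) if (t$gene_id == gene_id) strand <- t$strand
  cls <- vapply(frags, `[[`, "", "end_class")
  allb <- do.call(rbind, lapply(frags, `[[`, "blocks"))
  obs5 <- obs3 <- NA_real_
  if (any(cls == "TSS")) {
    b <- do.call(rbind, lapply(frags[cls == "TSS"], `[[`, "blocks"))
    obs5 <- if (strand == "+") min(b[, 1]) else max(b[, 2])
  }
  if (any(cls == "TES")) {
    b <- do.call(rbind, lapply(frags[cls == "TES"], `[[`, "blocks"))
    obs3 <- if (strand == "+") max(b[, 2]) else min(b[, 1])
  }
  juncs <- do.call(rbind, lapply(frags, function(fr) {
    b <- fr$blocks
    if (nrow(b) < 2) return(NULL)
    cbind(b[-nrow(b), 2], b[-1, 1])
  }))
  ok <- vapply(transcripts, function(t) {
    if (t$gene_id != gene_id) return(FALSE)
    if (!is.na(obs5) && abs(t$tss - obs5) > tol) return(FALSE)
    if (!is.na(obs3) && abs(t$tes - obs3) > tol) return(FALSE)
    ti <- pairiso:::transcript_introns(t)
    tk <- paste(ti[, 1], ti[, 2], sep = "-")
    if (!is.null(juncs) &&
        !all(paste(juncs[, 1], juncs[, 2], sep = "-") %in% tk)) return(FALSE)
    if (nrow(ti)) {
      for (k in seq_len(nrow(ti)))
        if (any(allb[, 1] < ti[k, 2] & allb[, 2] > ti[k, 1])) return(FALSE)
    }
    TRUE
  }, TRUE)
  sort(names(transcripts)[ok])
}

# concatenate SAM files (keep first header)
combine_sams <- function(out, ...) {
  paths <- c(...)
  lines <- readLines(paths[1])
  for (p in paths[-1]) {
    l <- readLines(p)
    lines <- c(lines, l[!startsWith(l, "@")])
  }
  writeLines(lines, out)
  out
}

# shared noise-free end-to-end run used by several acceptance criteria
e2e_default_run <- function() {
  ann <- make_synthetic_annotation(seed = 7)
  mol <- simulate_molecules(ann, n_cells = 6, depth_scale = 1, seed = 7)
  al <- emit_alignments(mol, ann)
  res <- run_pipeline(al$tss_sam, al$tes_sam, ann$transcripts)
  list(ann = ann, mol = mol, al = al, res = res)
}
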