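# Synthetic spike-in simulator: a SIRV-like multi-isoform annotation, an
# ERCC-like single-isoform abundance ladder, per-cell molecules carrying
# CB+UMI, and paired TSS/TES reads (FASTQ) plus pre-aligned records (SAM)
# with ground-truth tables. Everything is deterministic per seed
# (Mersenne-Twister).

.random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                 collapse = "")

# deterministic barcode for cell i (base-4 encoding), independent of seed
.cell_barcode <- function(i, cb_len = 6L) {
  digits <- integer(cb_len)
  x <- i - 1L
  for (k in seq_len(cb_len)) { digits[k] <- x %% 4L; x <- x %/% 4L }
  paste(c("A", "C", "G", "T")[rev(digits) + 1L], collapse = "")
}

#' Generate a synthetic spike-in annotation
#'
#' Builds a SIRV-like multi-isoform annotation plus an ERCC-like ladder of
#' single-isoform species, with a genome sequence and a ground-truth
#' abundance table, for end-to-end testing without external data.
#'
#' Each multi-isoform gene has a master exon chain (first exon, five
#' cassette middle exons, last exon); isoforms are distinct subsets of the
#' cassette exons, so any two isoforms of a gene each carry a splice
#' junction the other lacks and are therefore distinguishable from junction
#' evidence alone. Alternative TSS/TES offsets (multiples of 150 bp, well
#' beyond the default 50 bp end-matching tolerance) and an occasional
#' shifted acceptor add alternative-promoter, alternative-polyA and A3SS
#' variation. ERCC-like species are mono-exonic genes on a dedicated contig
#' whose expected abundances form a 2-fold ladder: 23 levels of 4 species,
#' `2^(-13) .. 2^9` molecules per cell (span > 4 orders of magnitude).
#'
#' @param n_isoforms Total isoforms across multi-isoform genes (default 69).
#' @param n_genes Number of multi-isoform genes (default 7).
#' @param n_ercc Number of single-isoform ladder species (default 92).
#' @param seed Integer seed; identical seeds give identical annotations.
#' @param sirv_abundance Expected molecules per cell for each multi-isoform
#'   transcript (default 10).
#' @return Object of class `synthetic_annotation`: list with `transcripts`
#'   (named list of `TranscriptModel`), `truth` (data.table: `species_id`,
#'   `transcript_id`, `gene_id`, `class`, `expected_abundance`), `genome`
#'   (named character vector of contig sequences), `params`.
#' @export
make_synthetic_annotation <- function(n_isoforms = 69L, n_genes = 7L,
                                      n_ercc = 92L, seed = 1L,
                                      sirv_abundance = 10) {
  stopifnot(n_isoforms >= n_genes, n_genes >= 1L)
  n_mid <- 5L
  per_gene <- rep(n_isoforms %/% n_genes, n_genes)
  extra <- n_isoforms %% n_genes
  if (extra > 0L) per_gene[seq_len(extra)] <- per_gene[seq_len(extra)] + 1L
  if (any(per_gene > 2^n_mid))
    stop("infeasible: more isoforms per gene than distinct cassette patterns")
  set.seed(seed, kind = "Mersenne-Twister")

  transcripts <- list()
  genome <- character(0)
  for (g in seq_len(n_genes)) {
    chrom <- sprintf("synSIRV%d", g)
    strand <- if (g %% 2L == 1L) "+" else "-"
    # master chain: terminal exons 420 bp, middle exons 120-300, introns 300-800
    ex_len <- c(420L, sample(120:300, n_mid, replace = TRUE), 420L)
    in_len <- sample(300:800, n_mid + 1L, replace = TRUE)
    starts <- integer(n_mid + 2L)
    starts[1L] <- 1000L
    for (k in seq_len(n_mid + 1L))
      starts[k + 1L] <- starts[k] + ex_len[k] + in_len[k]
    master <- cbind(start = starts, end = starts + ex_len)
    # distinct cassette patterns, all-middle-exons first (the reference form)
    pats <- c(list(rep(TRUE, n_mid)),
              sample(lapply(seq_len(2^n_mid - 1L) - 1L, function(b)
                as.logical(bitwAnd(b, 2L^(0:(n_mid - 1L))))), 2^n_mid - 1L))
    pats <- pats[seq_len(per_gene[g])]
    for (j in seq_len(per_gene[g])) {
      keep <- c(TRUE, pats[[j]], TRUE)
      exons <- master[keep, , drop = FALSE]
      # occasional shifted acceptor on the first kept middle exon (A3SS-like)
      if (j %% 4L == 2L && sum(keep[2:(n_mid + 1L)]) > 0L) {
        row <- 2L
        exons[row, 1L] <- exons[row, 1L] + 60L
      }
      tss_off <- 150L * ((j - 1L) %% 3L)
      tes_off <- 150L * ((j - 1L) %% 2L)
      n <- nrow(exons)
      if (strand == "+") {
        exons[1L, 1L] <- exons[1L, 1L] + tss_off
        exons[n, 2L] <- exons[n, 2L] - tes_off
      } else {
        exons[n, 2L] <- exons[n, 2L] - tss_off
        exons[1L, 1L] <- exons[1L, 1L] + tes_off
      }
      tid <- sprintf("SIRV%d%02d", g, j)
      transcripts[[tid]] <- transcript_model(tid, sprintf("SIRV%d", g),
                                             chrom, strand, exons)
    }
    genome[chrom] <- .random_dna(max(master[, 2L]) + 1000L)
  }
  sirv_truth <- data.table::rbindlist(lapply(transcripts, function(t)
    data.table::data.table(species_id = t$transcript_id,
                           transcript_id = t$transcript_id,
                           gene_id = t$gene_id, class = "sirv",
                           expected_abundance = sirv_abundance)))

  # ERCC-like ladder: mono-exonic species on one contig
  if (n_ercc > 0L) {
    n_levels <- 23L
    lens <- rep(c(400L, 600L, 800L, 1200L), length.out = n_ercc)
    # cycle the 23 levels (4 species each at the default 92); smaller
    # ladders spread across the full dynamic range instead of the bottom
    level <- if (n_ercc >= n_levels)
      ((seq_len(n_ercc) - 1L) %% n_levels) + 1L
    else as.integer(round(seq(1L, n_levels, length.out = n_ercc)))
    abund <- 2^(level - 14L)   # 2^-13 .. 2^9 molecules per cell
    pos <- 1000L
    ercc_truth <- vector("list", n_ercc)
    for (i in seq_len(n_ercc)) {
      tid <- sprintf("ERCC-%04d", i)
      gid <- sprintf("ERCCg-%04d", i)
      transcripts[[tid]] <- transcript_model(
        tid, gid, "synERCC", "+", cbind(pos, pos + lens[i]))
      ercc_truth[[i]] <- data.table::data.table(
        species_id = tid, transcript_id = tid, gene_id = gid,
        class = "ercc", expected_abundance = abund[i])
      pos <- pos + lens[i] + 500L
    }
    genome["synERCC"] <- .random_dna(pos + 1000L)
    truth <- data.table::rbindlist(c(list(sirv_truth), ercc_truth))
  } else {
    truth <- sirv_truth
  }
  structure(list(transcripts = transcripts, truth = truth, genome = genome,
                 params = list(n_isoforms = n_isoforms, n_genes = n_genes,
                               n_ercc = n_ercc, seed = seed,
                               sirv_abundance = sirv_abundance)),
            class = "synthetic_annotation")
}

#' @export
print.synthetic_annotation <- function(x, ...) {
  cat(sprintf("synthetic_annotation: %d transcripts (%d multi-isoform, %d ladder), %d contigs\n",
              length(x$transcripts), sum(x$truth$class == "sirv"),
              sum(x$truth$class == "ercc"), length(x$genome)))
  invisible(x)
}

#' Simulate captured molecules per cell
#'
#' Per cell and species, the number of captured molecules is
#' `Poisson(expected_abundance * depth_scale)`. Cell barcodes come from a
#' fixed per-cell list; UMIs are drawn uniformly from the 4^umi_len space.
#'
#' @param annotation A `synthetic_annotation` (or any object with `$truth`).
#' @param n_cells Number of cells (default 6).
#' @param depth_scale Multiplier on expected abundances (default 1).
#' @param seed Integer seed.
#' @param truth Optional subset of the truth table to simulate (default
#'   `annotation$truth`).
#' @param cb_len,umi_len Barcode and UMI lengths (defaults 6 and 12, the
#'   low-throughput dialect).
#' @return `data.table` of molecule records: `molecule_id`, `cell_id`,
#'   `cb`, `umi`, `transcript_id`, `gene_id`.
#' @export
simulate_molecules <- function(annotation, n_cells = 6L, depth_scale = 1,
                               seed = 1L, truth = annotation$truth,
                               cb_len = 6L, umi_len = 12L) {
  stopifnot(all(truth$expected_abundance > 0), depth_scale >= 0)
  set.seed(seed, kind = "Mersenne-Twister")
  cbs <- vapply(seq_len(n_cells), .cell_barcode, "", cb_len = cb_len)
  lam <- rep(truth$expected_abundance * depth_scale, times = n_cells)
  cell <- rep(seq_len(n_cells), each = nrow(truth))
  counts <- stats::rpois(length(lam), lam)
  if (sum(counts) == 0L)
    return(data.table::data.table(molecule_id = character(), cell_id = integer(),
                                  cb = character(), umi = character(),
                                  transcript_id = character(), gene_id = character()))
  idx <- rep(seq_along(lam), counts)
  n <- length(idx)
  umi_mat <- matrix(sample(c("A", "C", "G", "T"), n * umi_len, replace = TRUE),
                    nrow = n)
  mol <- data.table::data.table(
    molecule_id = sprintf("m%08d", seq_len(n)),
    cell_id = cell[idx],
    cb = cbs[cell[idx]],
    umi = do.call(paste0, as.data.frame(umi_mat)),
    transcript_id = truth$transcript_id[((idx - 1L) %% nrow(truth)) + 1L])
  mol$gene_id <- truth$gene_id[match(mol$transcript_id, truth$transcript_id)]
  mol[]
}

# spliced transcript sequence (sense strand)
transcript_sequence <- function(t, genome) {
  chrom_seq <- genome[[t$chrom]]
  parts <- substring(chrom_seq, t$exons[, 1L] + 1L, t$exons[, 2L])
  s <- paste(parts, collapse = "")
  if (t$strand == "-") reverse_complement(s) else s
}

# map a transcript-coordinate interval [a, b) (0-based, 5'->3') to genomic
# blocks (0-based half-open matrix)
tx_interval_to_blocks <- function(t, a, b) {
  widths <- t$exons[, 2L] - t$exons[, 1L]
  n <- nrow(t$exons)
  # exon order along the transcript
  ord <- if (t$strand == "+") seq_len(n) else rev(seq_len(n))
  w <- widths[ord]
  cum <- cumsum(c(0, w))
  blocks <- NULL
  for (k in seq_len(n)) {
    lo <- max(a, cum[k]); hi <- min(b, cum[k + 1L])
    if (lo >= hi) next
    off1 <- lo - cum[k]; off2 <- hi - cum[k]
    e <- t$exons[ord[k], ]
    if (t$strand == "+") {
      blocks <- rbind(blocks, c(e[1L] + off1, e[1L] + off2))
    } else {
      blocks <- rbind(blocks, c(e[2L] - off2, e[2L] - off1))
    }
  }
  blocks <- blocks[order(blocks[, 1L]), , drop = FALSE]
  dimnames(blocks) <- list(NULL, c("start", "end"))
  blocks
}

.apply_noise <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  n_err <- stats::rbinom(length(seqs), nchar(seqs), rate)
  hit <- which(n_err > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    pos <- sample.int(nchar(seqs[i]), n_err[i])
    s <- strsplit(seqs[i], "")[[1L]]
    for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1L)
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

#' Emit raw paired-library FASTQ reads for simulated molecules
#'
#' For each molecule, one TSS-library read sampled from the transcript 5'
#' end (`anchor + CB + UMI + tag + TSO + cDNA`) and one TES-library read
#' from the 3' end, emitted reverse-complemented per the TES orientation
#' convention (`revcomp(anchor + CB + UMI + tag + polyA + revcomp(3' cDNA))`).
#'
#' @param molecules Molecule table from [simulate_molecules()].
#' @param annotation The `synthetic_annotation` the molecules came from.
#' @param dialect A [dialect()] (default low-throughput).
#' @param noise Uniform per-base substitution rate (default 0).
#' @param seed Integer seed (used only when `noise > 0`).
#' @param cdna_len cDNA length sampled from each end (default 90).
#' @param polyA_len Length of the simulated polyA tail (default 18).
#' @param out_dir Output directory (created if needed).
#' @return List with `tss_fastq`, `tes_fastq`, `truth_tsv` paths and
#'   `n_reads`.
#' @export
emit_reads <- function(molecules, annotation, dialect = NULL, noise = 0,
                       seed = 1L, cdna_len = 90L, polyA_len = 18L,
                       out_dir = tempfile("simreads")) {
  if (is.null(dialect)) dialect <- pairiso::dialect("low_throughput")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed, kind = "Mersenne-Twister")
  txs <- annotation$transcripts[unique(molecules$transcript_id)]
  seqs <- vapply(txs, transcript_sequence, "", genome = annotation$genome)
  lens <- nchar(seqs)
  i <- match(molecules$transcript_id, names(txs))
  L <- pmin(cdna_len, lens[i])
  cdna5 <- substr(seqs[i], 1L, L)
  cdna3 <- substr(seqs[i], lens[i] - L + 1L, lens[i])
  construct <- paste0(dialect$anchor, molecules$cb, molecules$umi, dialect$tag)
  tss_reads <- paste0(construct, dialect$tso, cdna5)
  tes_reads <- reverse_complement(
    paste0(construct, strrep("A", polyA_len), reverse_complement(cdna3)))
  tss_reads <- .apply_noise(tss_reads, noise)
  tes_reads <- .apply_noise(tes_reads, noise)
  tss_ids <- paste0(molecules$molecule_id, ":tss")
  tes_ids <- paste0(molecules$molecule_id, ":tes")
  tss_fastq <- file.path(out_dir, "tss.fastq")
  tes_fastq <- file.path(out_dir, "tes.fastq")
  writeLines(paste0("@", tss_ids, "\n", tss_reads, "\n+\n",
                    strrep("I", nchar(tss_reads))), tss_fastq)
  writeLines(paste0("@", tes_ids, "\n", tes_reads, "\n+\n",
                    strrep("I", nchar(tes_reads))), tes_fastq)
  truth <- data.table::data.table(
    read_id = c(tss_ids, tes_ids),
    cb = rep(molecules$cb, 2L), umi = rep(molecules$umi, 2L),
    transcript_id = rep(molecules$transcript_id, 2L),
    end_class = rep(c("TSS", "TES"), each = nrow(molecules)))
  truth_tsv <- file.path(out_dir, "reads_truth.tsv")
  data.table::fwrite(truth, truth_tsv, sep = "\t", quote = FALSE)
  list(tss_fastq = tss_fastq, tes_fastq = tes_fastq, truth_tsv = truth_tsv,
       n_reads = 2L * nrow(molecules))
}

#' Emit pre-aligned SAM records for simulated molecules
#'
#' Bypasses the external aligner: writes spliced alignment records whose
#' block structure follows each molecule's exon chain, with `CB`/`UB`/`GX`
#' tags taken from the ground truth. Each molecule yields a 5'-terminal
#' fragment (TSS library) and a 3'-terminal fragment (TES library);
#' molecules of multi-isoform genes are additionally tiled with internal
#' fragments (alternating libraries) emulating the uniform coverage of
#' concatemer sequencing, so that every annotated feature of the generating
#' isoform is observed.
#'
#' @param molecules Molecule table from [simulate_molecules()].
#' @param annotation The `synthetic_annotation`.
#' @param out_dir Output directory.
#' @param frag_len Fragment length in transcript coordinates (default 90).
#' @param tile_step Tiling step for internal fragments (default 60).
#' @param tile `"multi"` (default: tile only multi-isoform genes), `"all"`,
#'   or `"none"`.
#' @return List with `tss_sam`, `tes_sam`, `truth_tsv` paths and counts.
#' @export
emit_alignments <- function(molecules, annotation, out_dir = tempfile("simaln"),
                            frag_len = 90L, tile_step = 60L,
                            tile = c("multi", "all", "none")) {
  tile <- match.arg(tile)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  txs <- annotation$transcripts
  genome <- annotation$genome
  n_iso <- table(vapply(txs, `[[`, "", "gene_id"))

  # per-transcript fragment layouts in transcript coordinates, cached
  layout <- new.env(parent = emptyenv())
  get_layout <- function(tid) {
    if (!is.null(layout[[tid]])) return(layout[[tid]])
    t <- txs[[tid]]
    len <- transcript_length(t)
    L <- min(frag_len, len)
    ivs <- rbind(c(0, L), c(len - L, len))
    cls <- c("TSS", "TES")
    do_tile <- tile == "all" ||
      (tile == "multi" && n_iso[[t$gene_id]] > 1L)
    if (do_tile && len > L) {
      st <- seq(0, len - L, by = tile_step)
      st <- setdiff(st, c(0, len - L))
      if (length(st)) {
        ivs <- rbind(ivs, cbind(st, st + L))
        cls <- c(cls, rep(c("TSS", "TES"), length.out = length(st)))
      }
    }
    blk <- lapply(seq_len(nrow(ivs)), function(k)
      tx_interval_to_blocks(t, ivs[k, 1L], ivs[k, 2L]))
    val <- list(blocks = blk, end_class = cls, t = t)
    assign(tid, val, envir = layout)
    val
  }

  mol_split <- split(seq_len(nrow(molecules)), molecules$transcript_id)
  rows <- vector("list", length(mol_split))
  ri <- 0L
  for (tid in names(mol_split)) {
    lay <- get_layout(tid)
    t <- lay$t
    nf <- length(lay$blocks)
    idx <- mol_split[[tid]]
    # precompute per-fragment SAM fields shared by all molecules of tid
    pos1 <- vapply(lay$blocks, function(b) b[1L, 1L] + 1, 0)
    cig <- vapply(lay$blocks, function(b) {
      n <- nrow(b)
      if (n == 1L) return(sprintf("%dM", as.integer(b[1L, 2L] - b[1L, 1L])))
      m <- as.integer(b[, 2L] - b[, 1L])
      gaps <- as.integer(b[-1L, 1L] - b[-n, 2L])
      paste0(paste0(m[-n], "M", gaps, "N", collapse = ""), m[n], "M")
    }, "")
    seqf <- vapply(lay$blocks, function(b)
      paste(substring(genome[[t$chrom]], b[, 1L] + 1L, b[, 2L]), collapse = ""),
      "")
    flag <- if (t$strand == "+") 0L else 16L
    ri <- ri + 1L
    rows[[ri]] <- data.table::data.table(
      qname = paste0(rep(molecules$molecule_id[idx], each = nf), ":f",
                     rep(seq_len(nf), times = length(idx))),
      flag = flag, rname = t$chrom,
      pos = rep(pos1, times = length(idx)),
      cigar = rep(cig, times = length(idx)),
      seq = rep(seqf, times = length(idx)),
      cb = rep(molecules$cb[idx], each = nf),
      umi = rep(molecules$umi[idx], each = nf),
      gene = t$gene_id,
      end_class = rep(lay$end_class, times = length(idx)))
  }
  aln <- data.table::rbindlist(rows[seq_len(ri)])
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(genome), nchar(genome)))
  for (ec in c("TSS", "TES")) {
    sub <- aln[aln$end_class == ec]
    lines <- sprintf("%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t*\tCB:Z:%s\tUB:Z:%s\tGX:Z:%s",
                     sub$qname, sub$flag, sub$rname, as.integer(sub$pos),
                     sub$cigar, sub$seq, sub$cb, sub$umi, sub$gene)
    writeLines(c(header, lines),
               file.path(out_dir, paste0(tolower(ec), ".sam")))
  }
  truth <- molecules[, c("molecule_id", "cb", "umi", "transcript_id", "gene_id")]
  truth_tsv <- file.path(out_dir, "molecules_truth.tsv")
  data.table::fwrite(truth, truth_tsv, sep = "\t", quote = FALSE)
  list(tss_sam = file.path(out_dir, "tss.sam"),
       tes_sam = file.path(out_dir, "tes.sam"),
       truth_tsv = truth_tsv, n_fragments = nrow(aln))
}
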