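# Read-structure detection: anchored CB/UMI extraction from the paired
# end-capture libraries, TES reorientation, and cDNA trimming.

#' Library dialect presets
#'
#' The two supported read dialects of the end-capture chemistry. Both share
#' the construct layout `anchor + CB + UMI + tag`, followed by the TSO and
#' the cDNA in TSS-library reads, or (after reverse complementation of the
#' raw read) by a polyA run and the cDNA in TES-library reads.
#'
#' * `low_throughput`: anchor `AACGCAGAGT`, 6 nt cell barcode at construct
#'   position 11, 12 nt UMI at position 17, tag `AGTTAACGCT`,
#'   TSO `GCAGGGTTGGG`.
#' * `tenx`: anchor `CTTCCGATCT`, 16 nt cell barcode, 12 nt UMI, polyT tag
#'   (matched as >= 8 consecutive T), TSO `GAGTACATGGG`.
#'
#' @param name `"low_throughput"` or `"tenx"`.
#' @param cb_len,umi_len Barcode/UMI lengths; defaults per dialect.
#' @return Object of class `Dialect`.
#' @export
dialect <- function(name = c("low_throughput", "tenx"),
                    cb_len = NULL, umi_len = NULL) {
  name <- match.arg(name)
  d <- switch(name,
    low_throughput = list(
      name = "low_throughput", anchor = "AACGCAGAGT", tag = "AGTTAACGCT",
      tag_type = "fixed", tso = "GCAGGGTTGGG",
      cb_start = 11L, cb_len = 6L, umi_start = 17L, umi_len = 12L),
    tenx = list(
      name = "tenx", anchor = "CTTCCGATCT", tag = "TTTTTTTTTT",
      tag_type = "polyT", tso = "GAGTACATGGG",
      cb_start = 11L, cb_len = 16L, umi_start = 27L, umi_len = 12L))
  if (!is.null(cb_len)) {
    d$cb_len <- as.integer(cb_len)
    d$umi_start <- d$cb_start + d$cb_len
  }
  if (!is.null(umi_len)) d$umi_len <- as.integer(umi_len)
  structure(d, class = "Dialect")
}

#' @export
print.Dialect <- function(x, ...) {
  cat(sprintf("Dialect %s: anchor=%s cb[%d+%d] umi[%d+%d] tag=%s tso=%s\n",
              x$name, x$anchor, x$cb_start, x$cb_len, x$umi_start, x$umi_len,
              if (x$tag_type == "polyT") "polyT(>=8)" else x$tag, x$tso))
  invisible(x)
}

#' Reverse complement of DNA sequences
#'
#' Vectorized over input; alphabet `ACGTN`. An involution:
#' `reverse_complement(reverse_complement(x)) == x`.
#'
#' @param seq Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(seq) {
  if (length(seq) == 0L) return(character(0))
  if (any(grepl("[^ACGTN]", seq)))
    stop("non-DNA character in sequence (alphabet is ACGTN)")
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

# vectorized Hamming distance between substrings of x starting at `at`
# (1-based, recycled) and a fixed pattern
.substr_mismatches <- function(x, at, pattern) {
  k <- nchar(pattern)
  mm <- integer(length(x))
  for (i in seq_len(k)) {
    mm <- mm + (substr(x, at + i - 1L, at + i - 1L) !=
                substr(pattern, i, i))
  }
  # positions running off the end count as all-mismatch
  mm[at + k - 1L > nchar(x)] <- k
  mm
}

# find anchor start (1-based) allowing <= max_mismatch; NA if absent.
# Fast path: exact prefix, then exact search, then sliding Hamming scan.
.find_anchor <- function(seqs, anchor, max_mismatch) {
  n <- length(seqs)
  pos <- rep(NA_integer_, n)
  at1 <- .substr_mismatches(seqs, 1L, anchor) <= max_mismatch
  pos[at1] <- 1L
  todo <- which(is.na(pos))
  if (length(todo)) {
    hit <- regexpr(anchor, seqs[todo], fixed = TRUE)
    found <- hit > 0L
    pos[todo[found]] <- hit[found]
  }
  if (max_mismatch > 0L) {
    todo <- which(is.na(pos))
    for (i in todo) {
      s <- seqs[i]
      L <- nchar(s) - nchar(anchor) + 1L
      if (L < 2L) next
      mm <- .substr_mismatches(rep(s, L - 1L), 2:L, anchor)
      j <- which(mm <= max_mismatch)
      if (length(j)) pos[i] <- j[1L] + 1L
    }
  }
  pos
}

# length of the homopolymer run of `base` starting at `at` (vectorized)
.run_length <- function(x, at, base, max_run = 60L) {
  run <- integer(length(x))
  alive <- rep(TRUE, length(x))
  for (i in seq_len(max_run)) {
    ch <- substr(x, at + i - 1L, at + i - 1L)
    alive <- alive & ch == base
    run <- run + alive
    if (!any(alive)) break
  }
  run
}

# Vectorized core parser. Returns a data.table with columns
# cb, umi, cdna, reject (NA_character_ when accepted).
parse_reads_vec <- function(seqs, dialect, end_class = c("TSS", "TES"),
                            max_mismatch = 1L, min_cdna = 30L,
                            min_polyA = 8L) {
  end_class <- match.arg(end_class)
  n <- length(seqs)
  out <- data.table::data.table(
    cb = NA_character_, umi = NA_character_, cdna = NA_character_,
    reject = rep(NA_character_, n))
  if (n == 0L) return(out)
  if (any(grepl("[^ACGTN]", seqs))) stop("non-DNA character in input reads")
  # TES reads carry the construct on the opposite strand: reorient first
  work <- if (end_class == "TES") reverse_complement(seqs) else seqs

  a <- .find_anchor(work, dialect$anchor, max_mismatch)
  out$reject[is.na(a)] <- "no_anchor"
  ok <- !is.na(a)
  base <- a - 1L  # construct offset: construct position p is read pos base+p

  cb <- substr(work, base + dialect$cb_start,
               base + dialect$cb_start + dialect$cb_len - 1L)
  umi <- substr(work, base + dialect$umi_start,
                base + dialect$umi_start + dialect$umi_len - 1L)
  tag_at <- base + dialect$umi_start + dialect$umi_len

  if (dialect$tag_type == "polyT") {
    trun <- .run_length(work, tag_at, "T")
    bad <- ok & trun < min_polyA
    after_tag <- tag_at + trun
  } else {
    tmm <- .substr_mismatches(work, tag_at, dialect$tag)
    bad <- ok & tmm > max_mismatch
    after_tag <- tag_at + nchar(dialect$tag)
  }
  out$reject[bad] <- "bad_tag"
  ok <- ok & !bad

  if (end_class == "TSS") {
    # cDNA follows the TSO
    tso_mm <- .substr_mismatches(work, after_tag, dialect$tso)
    bad <- ok & tso_mm > max_mismatch
    out$reject[bad] <- "no_tso"
    ok <- ok & !bad
    cdna <- substr(work, after_tag + nchar(dialect$tso), nchar(work))
  } else {
    # reoriented TES read: polyA run, then the reverse-complemented 3' cDNA
    arun <- .run_length(work, after_tag, "A")
    bad <- ok & arun < min_polyA
    out$reject[bad] <- "no_polyA"
    ok <- ok & !bad
    cdna_rc <- substr(work, after_tag + arun, nchar(work))
    cdna <- rep(NA_character_, n)
    if (any(ok)) cdna[ok] <- reverse_complement(cdna_rc[ok])
  }
  short <- ok & nchar(cdna) < min_cdna
  out$reject[short] <- "short_cdna"
  ok <- ok & !short

  out$cb[ok] <- cb[ok]
  out$umi[ok] <- umi[ok]
  out$cdna[ok] <- cdna[ok]
  out
}

#' Parse one raw read of an end-capture library
#'
#' Locates the dialect anchor, slices the cell barcode and UMI at the
#' dialect offsets, verifies the tag, and trims to cDNA. TSS-library reads
#' take the cDNA following the TSO; TES-library reads are reverse
#' complemented first, then the cDNA preceding the polyA tail is recovered
#' (returned in transcript-sense orientation, ending at the TES). Reads
#' lacking the complete structure are rejected with a reason code
#' (`no_anchor`, `bad_tag`, `no_tso`, `no_polyA`, `short_cdna`).
#'
#' @param seq Uppercase DNA string.
#' @param dialect A [dialect()] object.
#' @param end_class `"TSS"` or `"TES"` (which library the read is from).
#' @param max_mismatch Mismatches allowed in anchor/tag/TSO (default 1).
#' @param min_cdna Minimum cDNA length after trimming (default 30).
#' @return A list of class `TaggedRead` with `cb`, `umi`, `end_class`,
#'   `cdna`, `dialect`; or a list with a `reject` reason code.
#' @export
parse_read <- function(seq, dialect, end_class = c("TSS", "TES"),
                       max_mismatch = 1L, min_cdna = 30L) {
  end_class <- match.arg(end_class)
  r <- parse_reads_vec(seq, dialect, end_class, max_mismatch, min_cdna)
  if (!is.na(r$reject[1L]))
    return(structure(list(reject = r$reject[1L], end_class = end_class),
                     class = "TaggedRead"))
  structure(list(cb = r$cb[1L], umi = r$umi[1L], end_class = end_class,
                 cdna = r$cdna[1L], dialect = dialect$name, reject = NA_character_),
            class = "TaggedRead")
}

#' Tag a FASTQ of raw end-capture reads
#'
#' Parses every read with [parse_read()] semantics (vectorized), writes a
#' cDNA-only FASTQ whose headers encode `read_id|CB|UMI|end_class`, and a
#' sidecar TSV with one row per input read (`read_id, cb, umi, end_class,
#' reject_reason`). Order-preserving; every input read is counted exactly
#' once as parsed or rejected.
#'
#' @param fastq_in Input FASTQ path (optionally gzipped).
#' @param dialect A [dialect()] object.
#' @param end_class `"TSS"` or `"TES"`.
#' @param fastq_out Output cDNA FASTQ path (plain text; `.gz` honoured).
#' @param tsv_out Sidecar TSV path (default: `fastq_out` + `.tsv`).
#' @param max_mismatch,min_cdna See [parse_read()].
#' @return List with `n_input`, `n_parsed`, `rejects` (named counts by
#'   reason) and the output paths.
#' @export
tag_fastq <- function(fastq_in, dialect, end_class = c("TSS", "TES"),
                      fastq_out = tempfile(fileext = ".fastq"),
                      tsv_out = paste0(fastq_out, ".tsv"),
                      max_mismatch = 1L, min_cdna = 30L) {
  end_class <- match.arg(end_class)
  reads <- Biostrings::readDNAStringSet(fastq_in, format = "fastq")
  ids <- sub("\\s.*$", "", names(reads))
  seqs <- as.character(reads)
  parsed <- parse_reads_vec(seqs, dialect, end_class, max_mismatch, min_cdna)
  ok <- is.na(parsed$reject)
  con <- if (grepl("\\.gz$", fastq_out)) gzfile(fastq_out, "w") else file(fastq_out, "w")
  if (any(ok)) {
    hdr <- paste0("@", ids[ok], "|", parsed$cb[ok], "|", parsed$umi[ok],
                  "|", end_class)
    qual <- strrep("I", nchar(parsed$cdna[ok]))
    writeLines(paste(hdr, parsed$cdna[ok], "+", qual, sep = "\n"), con)
  }
  close(con)
  side <- data.table::data.table(
    read_id = ids, cb = parsed$cb, umi = parsed$umi, end_class = end_class,
    reject_reason = parsed$reject)
  data.table::fwrite(side, tsv_out, sep = "\t", na = "NA", quote = FALSE)
  rej <- table(parsed$reject[!ok])
  list(n_input = length(seqs), n_parsed = sum(ok),
       rejects = stats::setNames(as.integer(rej), names(rej)),
       fastq_out = fastq_out, tsv_out = tsv_out)
}
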