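#' Read a FASTQ file of small-RNA reads
#'
#' Parses 4-line FASTQ records into a `small_rna_reads` object. Sequences are
#' uppercased and U is mapped to T on ingest, so downstream comparisons work
#' on a single DNA alphabet. Malformed records raise an error naming the
#' offending line.
#'
#' @param path path to an uncompressed FASTQ file.
#' @return A `small_rna_reads` object: a list with character vectors
#'   `read_id` and `sequence`, and `qualities`, a list of integer Phred
#'   score vectors (or `NULL` elements when absent).
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "ACGU", "+", "IIII"), fq)
#' read_fastq(fq)$sequence  # "ACGT"
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) .stopf("FASTQ file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  n <- length(lines)
  if (n == 0L) return(small_rna_reads(character(), character(), list()))
  if (n %% 4L != 0L)
    .stopf("malformed FASTQ: %d lines is not a multiple of 4 (truncated record near line %d)",
           n, n)
  hd <- lines[seq(1L, n, by = 4L)]
  sq <- lines[seq(2L, n, by = 4L)]
  pl <- lines[seq(3L, n, by = 4L)]
  ql <- lines[seq(4L, n, by = 4L)]
  bad_hd <- which(!startsWith(hd, "@"))
  if (length(bad_hd))
    .stopf("malformed FASTQ: header without '@' at line %d", (bad_hd[1L] - 1L) * 4L + 1L)
  bad_pl <- which(!startsWith(pl, "+"))
  if (length(bad_pl))
    .stopf("malformed FASTQ: separator without '+' at line %d", (bad_pl[1L] - 1L) * 4L + 3L)
  bad_len <- which(nchar(sq) != nchar(ql))
  if (length(bad_len))
    .stopf("malformed FASTQ: sequence/quality length mismatch at line %d",
           (bad_len[1L] - 1L) * 4L + 2L)
  if (any(nchar(sq) == 0L))
    .stopf("malformed FASTQ: empty sequence at line %d",
           (which(nchar(sq) == 0L)[1L] - 1L) * 4L + 2L)
  ids <- sub("^@", "", vapply(strsplit(hd, "[ \t]"), `[`, "", 1L))
  seqs <- chartr("U", "T", toupper(sq))
  quals <- lapply(ql, function(q) utf8ToInt(q) - 33L)
  message(sprintf("read_fastq: %d records from %s", length(ids), path))
  small_rna_reads(ids, seqs, quals)
}

#' Construct a small_rna_reads object
#'
#' @param read_id character vector of read identifiers.
#' @param sequence character vector over \{A,C,G,T,N\} (same length).
#' @param qualities list of per-base integer Phred scores, or `NULL`.
#' @return A `small_rna_reads` object.
#' @export
small_rna_reads <- function(read_id, sequence, qualities = NULL) {
  if (length(read_id) != length(sequence))
    .stopf("read_id and sequence lengths differ")
  if (!is.null(qualities)) {
    if (length(qualities) != length(sequence))
      .stopf("qualities list length differs from sequence")
    bad <- which(vapply(seq_along(sequence), function(i) {
      !is.null(qualities[[i]]) && length(qualities[[i]]) != nchar(sequence[i])
    }, TRUE))
    if (length(bad))
      .stopf("qualities/sequence length mismatch for read %s", read_id[bad[1L]])
  }
  structure(list(read_id = as.character(read_id),
                 sequence = as.character(sequence),
                 qualities = qualities),
            class = "small_rna_reads")
}

#' @export
length.small_rna_reads <- function(x) length(x$read_id)

#' @export
print.small_rna_reads <- function(x, ...) {
  cat(sprintf("small_rna_reads: %d reads%s\n", length(x),
              if (is.null(x$qualities)) " (no qualities)" else ""))
  invisible(x)
}

#' Write reads to FASTQ
#'
#' @param reads a `small_rna_reads` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  quals <- reads$qualities
  if (is.null(quals))
    quals <- lapply(nchar(reads$sequence), function(n) rep.int(40L, n))
  qstr <- vapply(quals, function(q) intToUtf8(q + 33L), "")
  out <- as.vector(rbind(paste0("@", reads$read_id), reads$sequence, "+", qstr))
  writeLines(out, path)
  invisible(path)
}

#' Read a mature miRNA reference FASTA
#'
#' Loads a FASTA file into a named character vector of mature miRNA
#' sequences. Names are the first whitespace-delimited token of each header
#' and must be unique; sequences are uppercased with U mapped to T (miRBase
#' distributes mature sequences as RNA).
#'
#' @param path path to a FASTA file.
#' @return Named character vector, one uppercased T-alphabet sequence per
#'   miRNA.
#' @export
read_fasta_reference <- function(path) {
  if (!file.exists(path)) .stopf("FASTA file not found: %s", path)
  ss <- Biostrings::readBStringSet(path)
  nm <- vapply(strsplit(names(ss), "[ \t]"), `[`, "", 1L)
  dup <- nm[duplicated(nm)]
  if (length(dup))
    .stopf("duplicate reference name(s): %s", paste(unique(dup), collapse = ", "))
  seqs <- chartr("U", "T", toupper(as.character(ss)))
  if (any(nchar(seqs) == 0L))
    .stopf("empty sequence for reference entry: %s", nm[nchar(seqs) == 0L][1L])
  names(seqs) <- nm
  seqs
}

#' Write a named sequence set to FASTA
#'
#' @param sequences named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  ss <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Quality-control filter for long RNA-seq reads
#'
#' Applies the read-level QC used before alignment: keep a read only if its
#' mean Phred quality exceeds `min_q`, its length exceeds `min_len`, and its
#' longest single-base homopolymer run occupies less than
#' `max_homopolymer_frac` of the read. The decision is a pure function of the
#' sequence, the qualities and the thresholds.
#'
#' @param reads a `small_rna_reads` object.
#' @param min_q keep requires mean Phred strictly greater than this
#'   (default 20).
#' @param min_len keep requires length strictly greater than this
#'   (default 50 nt).
#' @param max_homopolymer_frac drop when the longest homopolymer run divided
#'   by read length reaches this fraction (default 0.5).
#' @return A data.frame with one row per read: `read_id`, `keep` (logical)
#'   and `reason` (`"pass"`, or a comma-separated list among
#'   `"low_quality"`, `"short"`, `"homopolymer"`). Reads without qualities
#'   skip the quality criterion with a warning.
#' @export
qc_filter_reads <- function(reads, min_q = 20, min_len = 50,
                            max_homopolymer_frac = 0.5) {
  n <- length(reads)
  len <- nchar(reads$sequence)
  run_frac <- vapply(reads$sequence, function(s) {
    r <- rle(strsplit(s, "", fixed = TRUE)[[1L]])
    max(r$lengths) / sum(r$lengths)
  }, 0, USE.NAMES = FALSE)
  has_q <- if (is.null(reads$qualities)) rep(FALSE, n)
           else vapply(reads$qualities, Negate(is.null), TRUE)
  mean_q <- rep(NA_real_, n)
  if (any(has_q))
    mean_q[has_q] <- vapply(reads$qualities[has_q], mean, 0)
  if (!all(has_q))
    .warnf("%d read(s) without qualities: quality criterion skipped for them",
           sum(!has_q))
  low_q <- has_q & mean_q <= min_q
  short <- len <= min_len
  homop <- run_frac >= max_homopolymer_frac
  reason <- vapply(seq_len(n), function(i) {
    r <- c(if (low_q[i]) "low_quality", if (short[i]) "short",
           if (homop[i]) "homopolymer")
    if (length(r)) paste(r, collapse = ",") else "pass"
  }, "")
  data.frame(read_id = reads$read_id,
             keep = !(low_q | short | homop),
             reason = reason,
             stringsAsFactors = FALSE)
}
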