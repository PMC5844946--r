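# Small-RNA processing: adapter trimming, exact-overlap assignment of reads
# to mature miRNAs, counting and the expression filter.

#' Trim 3' adapters from small-RNA reads
#'
#' Truncates each read at the first exact occurrence of the adapter's
#' leading `seed_len` bases. Reads without an adapter hit are kept
#' unmodified and flagged; trimmed reads whose insert is shorter than
#' `min_len` are discarded (they cannot reach the minimum assignment
#' overlap).
#'
#' @param reads a [small_rna_reads] object.
#' @param adapter adapter sequence (length >= `seed_len`).
#' @param seed_len number of adapter prefix bases matched exactly
#'   (default 8).
#' @param min_len minimum insert length retained (default 17 nt, the
#'   assignment overlap floor).
#' @return A list with `reads` (trimmed, surviving reads; qualities
#'   truncated alongside) and `status` (data.frame `read_id`, `status` in
#'   trimmed / no_adapter / discarded_short, `insert_len`).
#' @export
trim_adapter <- function(reads, adapter, seed_len = 8L, min_len = 17L) {
  if (nchar(adapter) < seed_len)
    .stopf("adapter (%d nt) shorter than seed_len (%d)", nchar(adapter), seed_len)
  seed <- toupper(substr(adapter, 1L, seed_len))
  hit <- as.integer(regexpr(seed, reads$sequence, fixed = TRUE))
  insert <- ifelse(hit > 0L, substr(reads$sequence, 1L, hit - 1L),
                   reads$sequence)
  ilen <- nchar(insert)
  status <- ifelse(hit > 0L,
                   ifelse(ilen >= min_len, "trimmed", "discarded_short"),
                   "no_adapter")
  keep <- status != "discarded_short"
  quals <- reads$qualities
  if (!is.null(quals)) {
    quals <- lapply(which(keep), function(i) {
      q <- quals[[i]]
      if (is.null(q)) NULL else q[seq_len(ilen[i])]
    })
  }
  list(reads = small_rna_reads(reads$read_id[keep], insert[keep], quals),
       status = data.frame(read_id = reads$read_id, status = status,
                           insert_len = ilen, stringsAsFactors = FALSE))
}

# All candidate (miRNA, offset) scores for one read: for each ungapped
# offset the overlap is the intersection of the read and miRNA spans; a
# candidate needs overlap >= min_overlap with zero mismatches inside it.
# Overhanging bases are ignored, not counted as mismatches.
.scan_read <- function(seq, reference, min_overlap) {
  lr <- nchar(seq)
  mirna <- character(0); offset <- integer(0); overlap <- integer(0)
  for (m in names(reference)) {
    ref <- reference[[m]]
    lm <- nchar(ref)
    if (min(lr, lm) < min_overlap) next
    # offset o = read start relative to miRNA start (0 = aligned starts)
    o <- seq.int(-(lr - min_overlap), lm - min_overlap)
    a <- pmax(0L, o)               # overlap start on miRNA (0-based)
    b <- pmin(lm, o + lr)          # overlap end (exclusive)
    ov <- b - a
    ok <- ov >= min_overlap
    if (!any(ok)) next
    o <- o[ok]; a <- a[ok]; ov <- ov[ok]
    rs <- a - o                    # overlap start on read (0-based)
    match <- substring(seq, rs + 1L, rs + ov) == substring(ref, a + 1L, a + ov)
    if (any(match)) {
      mirna <- c(mirna, rep.int(m, sum(match)))
      offset <- c(offset, o[match])
      overlap <- c(overlap, ov[match])
    }
  }
  if (!length(mirna)) return(NULL)
  data.frame(mirna = mirna, offset = offset, overlap = overlap,
             stringsAsFactors = FALSE)
}

#' Assign a small-RNA read to a mature miRNA
#'
#' Scores every miRNA at every ungapped offset; a candidate requires an
#' overlap (intersection of read and miRNA spans) of at least `min_overlap`
#' nucleotides with zero mismatches inside it, and the score is the overlap
#' length. A unique maximal-scoring miRNA yields an assignment; no candidate
#' yields `unassigned_no_hit`; a maximal score shared by two or more
#' distinct miRNAs yields `unassigned_ambiguous` (ambiguous reads are not
#' counted, preventing double counting). Reads shorter than `min_overlap`
#' are `unassigned_short`.
#'
#' @param sequence read sequence (character scalar, T alphabet).
#' @param reference named character vector of mature miRNA sequences.
#' @param min_overlap minimum mismatch-free overlap (default 17 nt).
#' @param read_id optional identifier carried into the result.
#' @return A one-row data.frame: `read_id`, `status`, `mirna`,
#'   `overlap_len`, `offset` (read start relative to miRNA start; negative
#'   when the read overhangs the 5' end).
#' @export
assign_read <- function(sequence, reference, min_overlap = 17L,
                        read_id = NA_character_) {
  if (length(reference) == 0L) .stopf("empty miRNA reference")
  if (min_overlap < 1L) .stopf("min_overlap must be >= 1")
  res <- data.frame(read_id = read_id, status = "unassigned_no_hit",
                    mirna = NA_character_, overlap_len = NA_integer_,
                    offset = NA_integer_, stringsAsFactors = FALSE)
  if (nchar(sequence) < min_overlap) {
    res$status <- "unassigned_short"
    return(res)
  }
  hits <- .scan_read(toupper(sequence), reference, as.integer(min_overlap))
  if (is.null(hits)) return(res)
  best <- hits[hits$overlap == max(hits$overlap), , drop = FALSE]
  if (length(unique(best$mirna)) > 1L) {
    res$status <- "unassigned_ambiguous"
    res$overlap_len <- best$overlap[1L]
    return(res)
  }
  res$status <- "assigned"
  res$mirna <- best$mirna[1L]
  res$overlap_len <- best$overlap[1L]
  res$offset <- best$offset[1L]
  res
}

#' Assign every read in a set
#'
#' Vectorized driver over [assign_read()] with a per-sequence cache
#' (identical sequences are scored once).
#'
#' @param reads a [small_rna_reads] object (adapter-trimmed).
#' @param reference named character vector of mature miRNA sequences.
#' @param min_overlap minimum mismatch-free overlap (default 17).
#' @return A data.frame with one row per read (columns as in
#'   [assign_read()]).
#' @export
assign_reads <- function(reads, reference, min_overlap = 17L) {
  uniq <- unique(reads$sequence)
  per_seq <- lapply(uniq, assign_read, reference = reference,
                    min_overlap = min_overlap)
  names(per_seq) <- uniq
  out <- do.call(rbind, per_seq[reads$sequence])
  out$read_id <- reads$read_id
  rownames(out) <- NULL
  out
}

#' Tally assigned reads into a miRNA count matrix
#'
#' @param assignments named list of per-sample assignment data.frames (as
#'   returned by [assign_reads()]); names are sample labels (unique).
#' @param mirnas miRNA name universe for the rows (default: union of
#'   assigned names).
#' @param config optional [pipeline_config()] stamped into provenance.
#' @return A `mirna_count_matrix`: list with `counts` (miRNA x sample
#'   integer matrix), `unassigned` (status x sample matrix) and
#'   `provenance` (config hash). Column sums of `counts` equal the number
#'   of assigned reads per sample.
#' @export
count_mirnas <- function(assignments, mirnas = NULL, config = NULL) {
  if (is.null(names(assignments)) || anyDuplicated(names(assignments)))
    .stopf("assignments must be a named list with unique sample labels")
  samples <- names(assignments)
  if (is.null(mirnas))
    mirnas <- sort(unique(unlist(lapply(assignments, function(a)
      a$mirna[a$status == "assigned"]))))
  counts <- matrix(0L, length(mirnas), length(samples),
                   dimnames = list(mirnas, samples))
  statuses <- c("assigned", "unassigned_short", "unassigned_no_hit",
                "unassigned_ambiguous")
  unas <- matrix(0L, length(statuses), length(samples),
                 dimnames = list(statuses, samples))
  for (s in samples) {
    a <- assignments[[s]]
    tab <- table(factor(a$mirna[a$status == "assigned"], levels = mirnas))
    counts[, s] <- as.integer(tab)
    st <- table(factor(a$status, levels = statuses))
    unas[, s] <- as.integer(st)
  }
  structure(list(counts = counts, unassigned = unas,
                 provenance = if (!is.null(config)) config_hash(config)
                              else NA_character_),
            class = "mirna_count_matrix")
}

#' @export
print.mirna_count_matrix <- function(x, ...) {
  cat(sprintf("mirna_count_matrix: %d miRNAs x %d samples (%d assigned reads)\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Filter miRNAs by expression
#'
#' Retains miRNAs reaching the expression floor of `min_count` reads. The
#' default mode keeps a miRNA when any single sample reaches `min_count`
#' (at least 10 reads per miRNA); mode `"total"` applies the floor to the
#' row total, and `"strict_gt"` requires a sample strictly above
#' `min_count` (a read count higher than 10 under the alternative reading).
#'
#' @param counts a miRNA x sample count matrix, or a `mirna_count_matrix`.
#' @param min_count expression floor (default 10).
#' @param mode one of `"max_per_sample"` (default), `"total"`,
#'   `"strict_gt"`.
#' @return A list with `counts` (filtered matrix), `retained` and
#'   `dropped` (character vectors of miRNA names).
#' @export
filter_expressed <- function(counts, min_count = 10L,
                             mode = c("max_per_sample", "total", "strict_gt")) {
  mode <- match.arg(mode)
  if (inherits(counts, "mirna_count_matrix")) counts <- counts$counts
  if (min_count < 0) .stopf("min_count must be >= 0")
  keep <- switch(mode,
                 max_per_sample = apply(counts, 1L, max) >= min_count,
                 total = rowSums(counts) >= min_count,
                 strict_gt = apply(counts, 1L, max) > min_count)
  list(counts = counts[keep, , drop = FALSE],
       retained = rownames(counts)[keep],
       dropped = rownames(counts)[!keep])
}
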