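# Independent brute-force oracles and tiny fixture builders. These stay
# deliberately naive (character-by-character loops, literal definitions) so
# they are independent of the implementation paths they check.

# Exhaustive read-to-miRNA scorer: every miRNA, every ungapped offset,
# per-character comparison. Returns the same status vocabulary as
# assign_read().
oracle_assign <- function(seq, reference, min_overlap = 17L) {
  lr <- nchar(seq)
  if (lr < min_overlap)
    return(list(status = "unassigned_short", mirna = NA, overlap = NA))
  rchars <- strsplit(seq, "")[[1]]
  best <- list()
  for (m in names(reference)) {
    mchars <- strsplit(reference[[m]], "")[[1]]
    lm <- length(mchars)
    for (o in seq(-lr + 1L, lm - 1L)) {
      ov <- 0L; mismatch <- FALSE
      for (i in seq_len(lr)) {           # i-th read base sits at miRNA pos o+i
        mp <- o + i
        if (mp >= 1L && mp <= lm) {
          ov <- ov + 1L
          if (rchars[i] != mchars[mp]) { mismatch <- TRUE; break }
        }
      }
      if (!mismatch && ov >= min_overlap)
        best[[length(best) + 1L]] <- list(mirna = m, overlap = ov, offset = o)
    }
  }
  if (!length(best))
    return(list(status = "unassigned_no_hit", mirna = NA, overlap = NA))
  ovs <- vapply(best, `[[`, 0L, "overlap")
  top <- best[ovs == max(ovs)]
  mirnas <- unique(vapply(top, `[[`, "", "mirna"))
  if (length(mirnas) > 1L)
    return(list(status = "unassigned_ambiguous", mirna = NA,
                overlap = max(ovs)))
  list(status = "assigned", mirna = mirnas, overlap = max(ovs))
}

# Literal BH step-up definition: padj_i = min over j with p_j >= p_i of
# m * p_j / rank_j, capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(m), function(i) {
    cand <- (m * p[p >= p[i]] / r[p >= p[i]])
    min(1, min(cand))
  }, 0)
}

# Brute-force geNorm M: pairwise SDs computed from scratch on a
# replicate-averaged wide table.
oracle_genorm_m <- function(wide, candidates) {
  vapply(candidates, function(j) {
    vs <- c()
    for (k in setdiff(candidates, j))
      vs <- c(vs, sd(wide[, j] - wide[, k]))
    mean(vs)
  }, 0)
}

random_dna <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                         replace = TRUE), collapse = "")

# small editing table built by hand
toy_pileup <- function(edited, total, site_class = "recoding",
                       groups = NULL) {
  n <- nrow(edited)
  sites <- data.frame(chrom = "chr1", pos = seq_len(n) * 10L, strand = "+",
                      site_class = site_class, gene = paste0("G", seq_len(n)),
                      aa_change = "Q/R", stringsAsFactors = FALSE)
  editing_site_table(sites, edited, total, groups = groups)
}
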