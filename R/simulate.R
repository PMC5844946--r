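# Synthetic-data generators. Every generator takes an explicit seed, is
# byte-deterministic given it, and returns its ground truth alongside the
# data so downstream calibration never re-derives truth from the generator.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

.random_seq <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                          replace = TRUE), collapse = "")

#' Generate a synthetic mature miRNA reference
#'
#' Produces unique random mature-miRNA sequences plus, optionally, "family
#' pairs": sequence pairs at Hamming distance 1 that share an identical
#' block of at least 17 nt (the mutated base is placed at the 3' terminus),
#' built to exercise ambiguous-assignment handling.
#'
#' @param n_mirnas total number of sequences (family-pair members included).
#' @param n_family_pairs number of Hamming-distance-1 pairs among them.
#' @param length_range integer range of sequence lengths; minimum 18 so a
#'   17-nt exact overlap is attainable.
#' @param seed integer RNG seed.
#' @return A list with `sequences` (named character vector,
#'   `mir-sim-<i>` / `mir-sim-<i>[ab]`) and `pairs` (data.frame of the
#'   paired names and the mutated position).
#' @export
gen_mirna_reference <- function(n_mirnas, n_family_pairs = 0,
                                length_range = c(20L, 23L), seed = 1L) {
  length_range <- as.integer(length_range)
  if (min(length_range) < 18L)
    .stopf("length_range minimum must be >= 18 nt (17-nt overlap must be attainable)")
  if (2L * n_family_pairs > n_mirnas)
    .stopf("n_family_pairs too large for n_mirnas")
  if (n_mirnas > 4^min(length_range) / 2)
    .stopf("infeasible: too many distinct sequences for length range")
  .with_seed(seed, {
    seqs <- character(0)
    n_singleton <- n_mirnas - 2L * n_family_pairs
    while (length(unique(seqs)) < n_singleton) {
      len <- sample(seq(length_range[1L], length_range[2L]), 1L)
      seqs <- unique(c(seqs, .random_seq(len)))
    }
    names(seqs) <- sprintf("mir-sim-%d", seq_along(seqs))
    pairs <- NULL
    for (p in seq_len(n_family_pairs)) {
      repeat {
        len <- sample(seq(length_range[1L], length_range[2L]), 1L)
        a <- .random_seq(len)
        base <- substr(a, len, len)
        alt <- sample(setdiff(c("A", "C", "G", "T"), base), 1L)
        b <- paste0(substr(a, 1L, len - 1L), alt)
        if (!a %in% seqs && !b %in% seqs && a != b) break
      }
      nm <- sprintf("mir-sim-fam%d", p)
      seqs[paste0(nm, "a")] <- a
      seqs[paste0(nm, "b")] <- b
      pairs <- rbind(pairs, data.frame(name_a = paste0(nm, "a"),
                                       name_b = paste0(nm, "b"),
                                       mutated_pos = len,
                                       stringsAsFactors = FALSE))
    }
    list(sequences = seqs, pairs = pairs)
  })
}

#' Simulate small-RNA sequencing reads
#'
#' Builds each read as (possibly 3'/5'-trimmed miRNA) + 3' adapter + random
#' padding, truncated to `read_length` — the layout of an untrimmed
#' small-RNA library where the insert is shorter than the read. IsomiR
#' end-variation is emulated by trimming 0-3 nt from either end with the
#' given probabilities. With probability `mismatch_rate` a read receives one
#' substitution placed so that every window of >= 17 nt of the insert
#' contains it, making the read unassignable under the zero-mismatch rule
#' whenever the insert is at most 33 nt.
#'
#' @param reference named character vector of mature miRNA sequences.
#' @param abundance named integer vector: reads to emit per miRNA.
#' @param adapter 3' adapter sequence (>= 8 nt, so the trimmer seed can
#'   find it).
#' @param isomir_shift_probs probabilities of trimming 0,1,2,3 nt at each
#'   end (default no shifts).
#' @param mismatch_rate per-read probability of the planted substitution.
#' @param read_length sequencer read length (default 50).
#' @param seed integer RNG seed.
#' @return A list with `reads` (a [small_rna_reads] object) and `truth`
#'   (data.frame `mirna`, `n_reads`).
#' @export
gen_small_rna_reads <- function(reference, abundance,
                                adapter = "TGGAATTCTCGGGTGCCAAGG",
                                isomir_shift_probs = c(1, 0, 0, 0),
                                mismatch_rate = 0, read_length = 50L,
                                seed = 1L) {
  if (nchar(adapter) < 8L)
    .stopf("adapter must be at least 8 nt (trimmer seed length)")
  if (any(abundance < 0)) .stopf("abundances must be >= 0")
  miss <- setdiff(names(abundance), names(reference))
  if (length(miss)) .stopf("abundance names not in reference: %s",
                           paste(miss, collapse = ", "))
  isomir_shift_probs <- isomir_shift_probs / sum(isomir_shift_probs)
  .with_seed(seed, {
    ids <- character(0); seqs <- character(0); src <- character(0)
    for (m in names(abundance)) {
      n <- abundance[[m]]
      if (n == 0) next
      full <- reference[[m]]
      for (i in seq_len(n)) {
        t5 <- sample(0:3, 1L, prob = isomir_shift_probs)
        t3 <- sample(0:3, 1L, prob = isomir_shift_probs)
        L <- nchar(full)
        insert <- substr(full, 1L + t5, L - t3)
        if (runif(1L) < mismatch_rate) {
          li <- nchar(insert)
          lo <- max(1L, li - 16L); hi <- min(17L, li)
          pos <- if (lo <= hi) sample(seq(lo, hi), 1L) else sample(li, 1L)
          base <- substr(insert, pos, pos)
          sub <- sample(setdiff(c("A", "C", "G", "T"), base), 1L)
          substr(insert, pos, pos) <- sub
        }
        read <- paste0(insert, adapter)
        if (nchar(read) < read_length)
          read <- paste0(read, .random_seq(read_length - nchar(read)))
        seqs <- c(seqs, substr(read, 1L, read_length))
        ids <- c(ids, sprintf("sim:%s:%d", m, i))
        src <- c(src, m)
      }
    }
    quals <- lapply(nchar(seqs), function(n) rep.int(37L, n))
    truth <- as.data.frame(table(factor(src, levels = names(abundance))),
                           stringsAsFactors = FALSE)
    names(truth) <- c("mirna", "n_reads")
    list(reads = small_rna_reads(ids, seqs, quals), truth = truth)
  })
}

#' Simulate a negative-binomial count matrix with known differential features
#'
#' Feature base means are drawn log-normally; a `de_fraction` of features get
#' their second-group mean multiplied by `2^lfc` (sign chosen at random per
#' feature). Counts are negative binomial with dispersion `nb_dispersion`
#' and per-sample depth factors, exercising upper-quartile normalization.
#'
#' @param n_features number of features.
#' @param n_per_group samples per group (length-2 vector or scalar).
#' @param de_fraction fraction of features that are truly differential.
#' @param lfc absolute log2 fold change applied to DE features.
#' @param nb_dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param base_mean meanlog scale for feature means (mean of the lognormal).
#' @param depth_range per-sample depth factors drawn uniformly in this range.
#' @param seed integer RNG seed.
#' @return A list with `counts` (matrix), `groups` (named vector,
#'   control/case), and `truth` (data.frame `feature`, `is_de`,
#'   `true_lfc`).
#' @export
gen_count_matrix <- function(n_features, n_per_group = 5L, de_fraction = 0,
                             lfc = 2, nb_dispersion = 0.15, base_mean = 150,
                             depth_range = c(0.7, 1.3), seed = 1L) {
  if (de_fraction < 0 || de_fraction > 1)
    .stopf("de_fraction must lie in [0,1]")
  if (length(n_per_group) == 1L) n_per_group <- rep(n_per_group, 2L)
  if (any(n_per_group < 2L)) .stopf("need >= 2 samples per group")
  .with_seed(seed, {
    n1 <- n_per_group[1L]; n2 <- n_per_group[2L]
    feats <- sprintf("feat-%04d", seq_len(n_features))
    mu <- rlnorm(n_features, meanlog = log(base_mean), sdlog = 0.8)
    n_de <- round(de_fraction * n_features)
    de_idx <- if (n_de > 0) sample(n_features, n_de) else integer(0)
    sign <- sample(c(-1, 1), n_de, replace = TRUE)
    true_lfc <- numeric(n_features)
    true_lfc[de_idx] <- sign * lfc
    mu2 <- mu * 2^true_lfc
    depth <- runif(n1 + n2, depth_range[1L], depth_range[2L])
    samples <- c(sprintf("ctrl-%d", seq_len(n1)), sprintf("case-%d", seq_len(n2)))
    counts <- matrix(0L, n_features, n1 + n2,
                     dimnames = list(feats, samples))
    size <- if (nb_dispersion > 0) 1 / nb_dispersion else Inf
    for (j in seq_len(n1 + n2)) {
      m <- (if (j <= n1) mu else mu2) * depth[j]
      counts[, j] <- if (is.finite(size)) rnbinom(n_features, mu = m, size = size)
                     else rpois(n_features, m)
    }
    groups <- setNames(rep(c("control", "case"), c(n1, n2)), samples)
    truth <- data.frame(feature = feats, is_de = seq_len(n_features) %in% de_idx,
                        true_lfc = true_lfc, stringsAsFactors = FALSE)
    list(counts = counts, groups = groups, truth = truth)
  })
}

#' Simulate beta-binomial editing pileups with group-specific site levels
#'
#' Per sample and site, an editing level is drawn
#' Beta(mean * concentration, (1 - mean) * concentration) around the site's
#' group mean, coverage is Poisson, and edited counts are binomial given
#' level and coverage. A `dropout` fraction of sample-site pairs gets zero
#' coverage, exercising the >= 3 covered samples per group filter.
#'
#' @param group_mean_levels numeric matrix (sites x 2, columns control/case)
#'   of mean editing levels in `[0,1]`; rownames become gene labels when
#'   `sites` is not supplied.
#' @param sites optional site annotation data.frame (as in
#'   [editing_site_table()]); autogenerated recoding sites otherwise.
#' @param concentration beta concentration parameter (> 0); larger =
#'   tighter sample levels around the group mean.
#' @param coverage mean per-sample read coverage (Poisson).
#' @param n_per_group samples per group.
#' @param dropout fraction of (site, sample) pairs forced to zero coverage.
#' @param seed integer RNG seed.
#' @return A list with `table` (an [editing_site_table] with groups
#'   attached) and `truth` (data.frame `site`, `mean_control`,
#'   `mean_case`).
#' @export
gen_editing_pileups <- function(group_mean_levels, sites = NULL,
                                concentration = 50, coverage = 100,
                                n_per_group = 6L, dropout = 0,
                                seed = 1L) {
  if (concentration <= 0) .stopf("concentration must be > 0")
  gm <- as.matrix(group_mean_levels)
  if (ncol(gm) != 2L) .stopf("group_mean_levels needs two columns (control, case)")
  if (any(gm < 0 | gm > 1)) .stopf("mean levels must lie in [0,1]")
  n_sites <- nrow(gm)
  if (is.null(sites)) {
    gene <- rownames(gm) %||% sprintf("GENE%d", seq_len(n_sites))
    sites <- data.frame(chrom = "chr1",
                        pos = 1000L + 100L * seq_len(n_sites),
                        strand = "+", site_class = "recoding",
                        gene = gene, aa_change = "Q/R",
                        stringsAsFactors = FALSE)
  }
  if (length(n_per_group) == 1L) n_per_group <- rep(n_per_group, 2L)
  .with_seed(seed, {
    n1 <- n_per_group[1L]; n2 <- n_per_group[2L]
    samples <- c(sprintf("ctrl-%d", seq_len(n1)), sprintf("case-%d", seq_len(n2)))
    groups <- setNames(rep(c("control", "case"), c(n1, n2)), samples)
    edited <- total <- matrix(0L, n_sites, n1 + n2,
                              dimnames = list(NULL, samples))
    for (j in seq_len(n1 + n2)) {
      m <- gm[, if (j <= n1) 1L else 2L]
      lev <- m
      inner <- m > 0 & m < 1
      if (any(inner))
        lev[inner] <- rbeta(sum(inner), m[inner] * concentration,
                            (1 - m[inner]) * concentration)
      cov <- rpois(n_sites, coverage)
      if (dropout > 0) cov[runif(n_sites) < dropout] <- 0L
      total[, j] <- cov
      edited[, j] <- rbinom(n_sites, cov, lev)
    }
    truth <- data.frame(site = seq_len(n_sites), gene = sites$gene,
                        mean_control = gm[, 1L], mean_case = gm[, 2L],
                        stringsAsFactors = FALSE)
    list(table = editing_site_table(sites, edited, total, groups = groups),
         truth = truth)
  })
}

#' Simulate an RT-qPCR Ct table with housekeepers of graded stability
#'
#' Ct values are built as gene baseline + shared per-sample offset (RNA
#' input/loading, which exact housekeeper normalization cancels) + gene-level
#' instability noise − group effect (target genes, case group only) +
#' replicate noise. The intended downstream quantity is
#' `-ddCt = group_log2_effect` for each target.
#'
#' @param targets character vector of target gene names.
#' @param housekeepers named numeric vector: per-housekeeper instability SD
#'   in cycles (0 = perfectly stable); >= 3 required.
#' @param group_log2_effects named numeric vector (per target): case-group
#'   log2 up-regulation (Ct decreases by this amount).
#' @param replicate_sd technical replicate SD in cycles.
#' @param n_per_group samples per group (>= 2).
#' @param n_replicates technical replicates per (sample, gene) (>= 2).
#' @param sample_sd SD of the shared per-sample offset (cycles).
#' @param seed integer RNG seed.
#' @return A list with `ct` (long data.frame: sample, group, gene,
#'   replicate, ct), `housekeepers` (names) and `truth` (data.frame
#'   `gene`, `true_log2_rel`).
#' @export
gen_ct_table <- function(targets, housekeepers, group_log2_effects,
                         replicate_sd = 0.1, n_per_group = 5L,
                         n_replicates = 3L, sample_sd = 0.5, seed = 1L) {
  if (length(housekeepers) < 3L) .stopf("need >= 3 candidate housekeepers")
  if (n_replicates < 2L) .stopf("need >= 2 technical replicates")
  if (any(n_per_group < 2L)) .stopf("n_per_group must be >= 2")
  if (length(n_per_group) == 1L) n_per_group <- rep(n_per_group, 2L)
  miss <- setdiff(targets, names(group_log2_effects))
  group_log2_effects[miss] <- 0
  .with_seed(seed, {
    n1 <- n_per_group[1L]; n2 <- n_per_group[2L]
    samples <- c(sprintf("ctrl-%d", seq_len(n1)), sprintf("case-%d", seq_len(n2)))
    groups <- setNames(rep(c("control", "case"), c(n1, n2)), samples)
    genes <- c(names(housekeepers), targets)
    base <- setNames(runif(length(genes), 18, 28), genes)
    samp_off <- setNames(rnorm(length(samples), 0, sample_sd), samples)
    rows <- vector("list", length(samples) * length(genes))
    k <- 0L
    for (s in samples) for (g in genes) {
      mu <- base[[g]] + samp_off[[s]]
      if (g %in% names(housekeepers) && housekeepers[[g]] > 0)
        mu <- mu + rnorm(1L, 0, housekeepers[[g]])
      if (g %in% targets && groups[[s]] == "case")
        mu <- mu - group_log2_effects[[g]]
      k <- k + 1L
      rows[[k]] <- data.frame(sample = s, group = groups[[s]], gene = g,
                              replicate = seq_len(n_replicates),
                              ct = mu + rnorm(n_replicates, 0, replicate_sd),
                              stringsAsFactors = FALSE)
    }
    ct <- do.call(rbind, rows)
    truth <- data.frame(gene = targets,
                        true_log2_rel = unname(group_log2_effects[targets]),
                        stringsAsFactors = FALSE)
    list(ct = ct, housekeepers = names(housekeepers), truth = truth)
  })
}
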