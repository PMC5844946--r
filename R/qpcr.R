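# RT-qPCR: reference-gene stability (geNorm-M and a NormFinder-style
# variance decomposition) and delta-delta-Ct relative quantification
# against the control-group calibrator.

# replicate-averaged sample x gene Ct matrix from the long table
.ct_wide <- function(ct) {
  agg <- stats::aggregate(ct ~ sample + gene, data = ct, FUN = mean)
  samples <- unique(ct$sample); genes <- unique(ct$gene)
  m <- matrix(NA_real_, length(samples), length(genes),
              dimnames = list(samples, genes))
  m[cbind(match(agg$sample, samples), match(agg$gene, genes))] <- agg$ct
  m
}

.ct_groups <- function(ct) {
  u <- unique(ct[, c("sample", "group")])
  if (anyDuplicated(u$sample))
    .stopf("sample '%s' carries more than one group label",
           u$sample[duplicated(u$sample)][1L])
  setNames(u$group, u$sample)
}

#' geNorm expression-stability measure M
#'
#' For candidate genes j, k the pairwise variation `V_jk` is the standard
#' deviation over samples of the Ct difference `Ct_j - Ct_k` (the log-ratio
#' on the Ct scale); `M_j` is the mean of `V_jk` over all other candidates.
#' Lower M = more stable. Iteratively excluding the highest-M gene and
#' recomputing yields a stability ranking that ends in the most stable
#' pair (which cannot be resolved further).
#'
#' @param ct long Ct table (see [read_ct_table()]); replicates are averaged
#'   per (sample, gene).
#' @param candidates candidate housekeeper gene names (>= 3); every
#'   candidate must be measured in every sample.
#' @return A list with `m` (named vector, M on the full candidate set),
#'   `ranking` (gene names, most stable first; the final two genes tie)
#'   and `exclusion_order` (least stable first).
#' @export
genorm_m <- function(ct, candidates) {
  if (length(candidates) < 3L) .stopf("geNorm needs >= 3 candidates")
  wide <- .ct_wide(ct)
  miss <- setdiff(candidates, colnames(wide))
  if (length(miss)) .stopf("candidate(s) not measured: %s",
                           paste(miss, collapse = ", "))
  sub <- wide[, candidates, drop = FALSE]
  if (anyNA(sub)) {
    bad <- which(colSums(is.na(sub)) > 0)[1L]
    .stopf("candidate '%s' missing in some sample", candidates[bad])
  }
  m_of <- function(genes) {
    vapply(genes, function(j) {
      mean(vapply(setdiff(genes, j), function(k) sd(sub[, j] - sub[, k]), 0))
    }, 0)
  }
  m_full <- m_of(candidates)
  remaining <- candidates
  exclusion <- character(0)
  while (length(remaining) > 2L) {
    m_cur <- m_of(remaining)
    worst <- names(which.max(m_cur))
    exclusion <- c(exclusion, worst)
    remaining <- setdiff(remaining, worst)
  }
  list(m = m_full, ranking = c(remaining, rev(exclusion)),
       exclusion_order = exclusion)
}

#' NormFinder-style stability
#'
#' Ct values are centered per sample across the candidate set (removing the
#' shared abundance/loading component); per gene the measure combines the
#' inter-group bias of the centered residuals with their SE-scaled
#' intra-group variation:
#' `stability_g = mean over groups a of sqrt(d_ag^2 + v_ag / n_a)` where
#' `d_ag` is the group-mean deviation of gene g's residuals from its
#' overall mean and `v_ag` the within-group variance. Larger = less
#' stable. This follows the published intra/inter-group variance
#' decomposition of the NormFinder model rather than reproducing the Excel
#' applet bit-for-bit.
#'
#' @inheritParams genorm_m
#' @param groups optional named group vector (default: from the Ct table).
#' @return A list with `stability` (named vector) and `ranking` (most
#'   stable first).
#' @export
normfinder_stability <- function(ct, candidates, groups = NULL) {
  if (length(candidates) < 3L) .stopf("NormFinder needs >= 3 candidates")
  groups <- groups %||% .ct_groups(ct)
  wide <- .ct_wide(ct)
  miss <- setdiff(candidates, colnames(wide))
  if (length(miss)) .stopf("candidate(s) not measured: %s",
                           paste(miss, collapse = ", "))
  sub <- wide[, candidates, drop = FALSE]
  if (anyNA(sub)) {
    bad <- which(colSums(is.na(sub)) > 0)[1L]
    .stopf("candidate '%s' missing in some sample", candidates[bad])
  }
  g <- .check_groups(groups, rownames(sub))
  resid <- sweep(sub, 1L, rowMeans(sub))       # sample-centered Ct
  resid <- sweep(resid, 2L, colMeans(resid))   # per-gene overall mean 0
  lv <- unique(g)
  stab <- vapply(candidates, function(j) {
    mean(vapply(lv, function(a) {
      r <- resid[g == a, j]
      sqrt(mean(r)^2 + var(r) / length(r))
    }, 0))
  }, 0)
  list(stability = stab, ranking = names(sort(stab)))
}

#' Consensus housekeeper selection
#'
#' Merges the geNorm and NormFinder rankings: genes in both methods'
#' top-k enter first (in geNorm order), then remaining slots are filled by
#' geNorm rank. geNorm thus breaks every disagreement, which is the
#' documented tie rule.
#'
#' @param genorm result of [genorm_m()].
#' @param normfinder result of [normfinder_stability()].
#' @param k number of housekeepers to select (default 3).
#' @return Character vector of k gene names.
#' @export
select_housekeepers <- function(genorm, normfinder, k = 3L) {
  rg <- genorm$ranking; rn <- normfinder$ranking
  if (k > length(rg)) .stopf("k exceeds the number of candidates")
  consensus <- rg[rg %in% intersect(head(rg, k), head(rn, k))]
  extra <- setdiff(rg, consensus)
  head(c(consensus, extra), k)
}

#' Reference-gene stability report
#'
#' Runs both stability methods and the consensus selection.
#'
#' @inheritParams genorm_m
#' @param groups optional named group vector.
#' @param k housekeepers to select (default 3).
#' @return A list with `genorm`, `normfinder`, `table` (per-gene M and
#'   stability, ranked) and `selected`.
#' @export
stability_report <- function(ct, candidates, groups = NULL, k = 3L) {
  gn <- genorm_m(ct, candidates)
  nf <- normfinder_stability(ct, candidates, groups)
  tab <- data.frame(gene = candidates,
                    genorm_m = unname(gn$m[candidates]),
                    genorm_rank = match(candidates, gn$ranking),
                    normfinder_stability = unname(nf$stability[candidates]),
                    normfinder_rank = match(candidates, nf$ranking),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$genorm_rank), ]
  rownames(tab) <- NULL
  list(genorm = gn, normfinder = nf, table = tab,
       selected = select_housekeepers(gn, nf, k))
}

#' Delta-delta-Ct relative quantification
#'
#' Per sample, `dCt = Ct_target - mean(Ct of the selected housekeepers)`
#' (replicates averaged first); `ddCt = dCt - mean(dCt over the control
#' group)`, making the control group the calibrator; the reported
#' log2-scale relative expression is `log2_rel = -ddCt` (log2 of
#' `2^-ddCt`), so up-regulated targets are positive and the control-group
#' mean is 0 by construction.
#'
#' @param ct long Ct table.
#' @param target target gene (not among `housekeepers`).
#' @param housekeepers housekeeper gene names used for normalization.
#' @param groups optional named group vector (default: from the table).
#' @param control control-group label (autodetected otherwise).
#' @return A list with `per_sample` (data.frame `sample`, `group`,
#'   `delta_ct`, `ddct`, `log2_rel`), `summary` (per group mean, sd, n)
#'   and `p` (two-tailed Welch t on log2_rel between groups). Samples
#'   missing the target or any housekeeper are excluded with a warning.
#' @examples
#' sim <- gen_ct_table("TARG", c(HK1 = 0, HK2 = 0.05, HK3 = 0.1),
#'                     c(TARG = 1), seed = 5)
#' ddct_quantify(sim$ct, "TARG", sim$housekeepers)$summary
#' @export
ddct_quantify <- function(ct, target, housekeepers, groups = NULL,
                          control = NULL) {
  if (target %in% housekeepers)
    .stopf("target '%s' cannot be a housekeeper", target)
  groups <- groups %||% .ct_groups(ct)
  wide <- .ct_wide(ct)
  need <- c(target, housekeepers)
  miss <- setdiff(need, colnames(wide))
  if (length(miss)) .stopf("gene(s) absent from Ct table: %s",
                           paste(miss, collapse = ", "))
  ok <- rowSums(is.na(wide[, need, drop = FALSE])) == 0
  if (!all(ok))
    .warnf("excluding sample(s) with missing Ct: %s",
           paste(rownames(wide)[!ok], collapse = ", "))
  wide <- wide[ok, , drop = FALSE]
  g <- .check_groups(groups, rownames(wide))
  lv <- .group_levels(g, control)
  if (!any(g == lv[1L])) .stopf("control group is empty")
  dct <- wide[, target] - rowMeans(wide[, housekeepers, drop = FALSE])
  ddct <- dct - mean(dct[g == lv[1L]])
  per_sample <- data.frame(sample = rownames(wide), group = g,
                           delta_ct = unname(dct), ddct = unname(ddct),
                           log2_rel = -unname(ddct),
                           stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(lv, function(grp) {
    v <- per_sample$log2_rel[per_sample$group == grp]
    data.frame(group = grp, mean_log2_rel = mean(v),
               sd_log2_rel = if (length(v) > 1L) sd(v) else NA_real_,
               n = length(v), stringsAsFactors = FALSE)
  }))
  wt <- .welch_p(per_sample$log2_rel[g == lv[2L]],
                 per_sample$log2_rel[g == lv[1L]])
  list(per_sample = per_sample, summary = summ, p = wt$p, flag = wt$flag)
}
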