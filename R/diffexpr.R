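# Count-based differential expression: upper-quartile normalization,
# log2 fold changes, intra-/inter-condition pairwise ratio diagnostics,
# Welch t-tests, BH correction and the selection rule.

#' Upper-quartile normalization
#'
#' Each sample's size factor is the 75th percentile (linear-interpolation
#' quantile, R type 7) of its counts over features that are nonzero in at
#' least one sample. Counts are divided by the size factor and rescaled by
#' the geometric mean of all size factors, preserving the overall scale;
#' afterwards all samples have equal upper quartiles over that feature set.
#'
#' @param mat feature x sample nonnegative matrix.
#' @return A list with `matrix` (normalized values) and `size_factors`
#'   (named positive scalars; an all-zero qualifying column is an error
#'   naming the sample).
#' @export
uq_normalize <- function(mat) {
  mat <- as.matrix(mat)
  if (any(mat < 0)) .stopf("counts must be nonnegative")
  qual <- rowSums(mat) > 0
  if (!any(qual)) .stopf("no feature is nonzero in any sample")
  sf <- apply(mat[qual, , drop = FALSE], 2L, quantile, probs = 0.75,
              type = 7, names = FALSE)
  zero <- which(sf <= 0)
  if (length(zero))
    .stopf("upper quartile is zero for sample '%s'",
           colnames(mat)[zero[1L]] %||% as.character(zero[1L]))
  scale <- exp(mean(log(sf)))
  norm <- sweep(mat, 2L, sf, `/`) * scale
  list(matrix = norm, size_factors = setNames(sf, colnames(mat)))
}

#' Per-feature log2 fold change (case over control)
#'
#' `log2((mean_case + c) / (mean_ctrl + c))` on normalized values, with
#' pseudocount `c` keeping the ratio finite at zero counts.
#'
#' @param mat normalized feature x sample matrix.
#' @param groups group labels (named by sample, two levels).
#' @param pseudocount `c > 0`, or 0 when all group means are positive.
#' @param control optional control-group label (autodetected otherwise).
#' @return A data.frame: `feature`, `mean_ctrl`, `mean_case`, `log2fc`.
#' @export
log2_fold_change <- function(mat, groups, pseudocount = 1, control = NULL) {
  g <- .check_groups(groups, colnames(mat))
  lv <- .group_levels(g, control)
  m_ctrl <- rowMeans(mat[, g == lv[1L], drop = FALSE])
  m_case <- rowMeans(mat[, g == lv[2L], drop = FALSE])
  if (pseudocount < 0) .stopf("pseudocount must be >= 0")
  if (pseudocount == 0 && any(m_ctrl == 0 | m_case == 0))
    .stopf("pseudocount 0 with a zero group mean: fold change undefined")
  data.frame(feature = rownames(mat) %||% as.character(seq_len(nrow(mat))),
             mean_ctrl = m_ctrl, mean_case = m_case,
             log2fc = log2((m_case + pseudocount) / (m_ctrl + pseudocount)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Intra- and inter-condition pairwise log2 ratios
#'
#' For each feature, the intra set holds log2 ratios over all unordered
#' within-group sample pairs (both groups pooled) and the inter set holds
#' ratios over all case-vs-control ordered pairs; with group sizes (n1, n2)
#' the set sizes are `choose(n1,2) + choose(n2,2)` and `n1 * n2`.
#'
#' @inheritParams log2_fold_change
#' @return A list with `intra` and `inter` (each a feature-indexed list of
#'   numeric vectors) and `summary` (data.frame `feature`,
#'   `intra_fc_spread` = SD of intra ratios, `inter_fc_mean` = mean inter
#'   ratio, `n_intra`, `n_inter`). A group of size 1 yields an empty intra
#'   contribution and a warning.
#' @export
pairwise_fc <- function(mat, groups, pseudocount = 1, control = NULL) {
  g <- .check_groups(groups, colnames(mat))
  lv <- .group_levels(g, control)
  idx_c <- which(g == lv[1L]); idx_t <- which(g == lv[2L])
  if (length(idx_c) < 2L || length(idx_t) < 2L)
    .warnf("a group has fewer than 2 samples: its intra set is empty")
  lx <- log2(mat + pseudocount)
  pair_idx <- function(idx) {
    if (length(idx) < 2L) return(NULL)
    cb <- utils::combn(idx, 2L)
    cb
  }
  cb_c <- pair_idx(idx_c); cb_t <- pair_idx(idx_t)
  inter_grid <- expand.grid(case = idx_t, ctrl = idx_c)
  n_feat <- nrow(mat)
  intra <- vector("list", n_feat); inter <- vector("list", n_feat)
  for (i in seq_len(n_feat)) {
    v <- lx[i, ]
    ia <- c(if (!is.null(cb_c)) v[cb_c[1L, ]] - v[cb_c[2L, ]],
            if (!is.null(cb_t)) v[cb_t[1L, ]] - v[cb_t[2L, ]])
    intra[[i]] <- unname(ia)
    inter[[i]] <- unname(v[inter_grid$case] - v[inter_grid$ctrl])
  }
  feats <- rownames(mat) %||% as.character(seq_len(n_feat))
  names(intra) <- names(inter) <- feats
  summary <- data.frame(feature = feats,
                        intra_fc_spread = vapply(intra, function(x)
                          if (length(x) > 1L) sd(x) else NA_real_, 0),
                        inter_fc_mean = vapply(inter, mean, 0),
                        n_intra = lengths(intra), n_inter = lengths(inter),
                        row.names = NULL, stringsAsFactors = FALSE)
  list(intra = intra, inter = inter, summary = summary)
}

#' Per-feature two-tailed t-test between conditions
#'
#' Default mode `log_expression` applies a Welch two-tailed t-test to
#' `log2(normalized + c)` between groups. Mode `fc_contrast` is the literal
#' intra/inter comparison: a two-sample Welch t of the inter-condition
#' pairwise log2 ratios against the pooled intra-condition ratios.
#' Degenerate features (zero variance in both groups) get p = 1 when the
#' means are equal and the smallest representable double otherwise, with
#' the convention flagged.
#'
#' @inheritParams log2_fold_change
#' @param mode `"log_expression"` (default) or `"fc_contrast"`.
#' @return A data.frame: `feature`, `p`, `flag`.
#' @export
de_test <- function(mat, groups, mode = c("log_expression", "fc_contrast"),
                    pseudocount = 1, control = NULL) {
  mode <- match.arg(mode)
  g <- .check_groups(groups, colnames(mat))
  lv <- .group_levels(g, control)
  if (sum(g == lv[1L]) < 2L || sum(g == lv[2L]) < 2L)
    .stopf("need >= 2 samples per group for testing")
  feats <- rownames(mat) %||% as.character(seq_len(nrow(mat)))
  if (mode == "log_expression") {
    lx <- log2(mat + pseudocount)
    res <- lapply(seq_len(nrow(mat)), function(i)
      .welch_p(lx[i, g == lv[2L]], lx[i, g == lv[1L]]))
  } else {
    pw <- pairwise_fc(mat, groups, pseudocount, control)
    res <- lapply(seq_len(nrow(mat)), function(i)
      .welch_p(pw$inter[[i]], pw$intra[[i]]))
  }
  data.frame(feature = feats,
             p = vapply(res, `[[`, 0, "p"),
             flag = vapply(res, `[[`, "", "flag"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: `padj_i` is the minimum over `j` with
#' `p_j >= p_i` of `m * p_j / rank_j`, capped at 1; input order preserved.
#'
#' @param p numeric vector of raw p-values in `[0,1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    .stopf("p-values must lie in [0,1]")
  p.adjust(p, method = "BH")
}

#' Select differentially expressed features
#'
#' Applies the selection rule |log2FC| > `lfc_threshold` AND
#' `padj < alpha`, both strict.
#'
#' @param results data.frame carrying `feature`, `log2fc`, `padj`.
#' @param lfc_threshold |log2FC| threshold (default 1, strict).
#' @param alpha adjusted-p threshold (default 0.05, strict).
#' @return Character vector of selected feature names.
#' @export
select_de <- function(results, lfc_threshold = 1, alpha = 0.05) {
  stopifnot(all(c("feature", "log2fc", "padj") %in% names(results)))
  results$feature[abs(results$log2fc) > lfc_threshold &
                    results$padj < alpha]
}

#' Run the complete differential-expression procedure
#'
#' Upper-quartile normalization, log2 fold changes, per-feature Welch
#' t-test, BH adjustment, pairwise-ratio diagnostics and selection, in one
#' call.
#'
#' @param counts raw feature x sample count matrix.
#' @inheritParams de_test
#' @param lfc_threshold,alpha selection thresholds (strict).
#' @return A data.frame (one row per feature): `feature`, `mean_ctrl`,
#'   `mean_case`, `log2fc`, `intra_fc_spread`, `inter_fc_mean`, `p`,
#'   `padj`, `selected`.
#' @examples
#' sim <- gen_count_matrix(50, n_per_group = 4, de_fraction = 0.2,
#'                         lfc = 3, seed = 11)
#' res <- run_de(sim$counts, sim$groups)
#' head(res[order(res$padj), ])
#' @export
run_de <- function(counts, groups, mode = "log_expression", pseudocount = 1,
                   lfc_threshold = 1, alpha = 0.05, control = NULL) {
  nm <- uq_normalize(counts)
  lfc <- log2_fold_change(nm$matrix, groups, pseudocount, control)
  tst <- de_test(nm$matrix, groups, mode, pseudocount, control)
  pw <- pairwise_fc(nm$matrix, groups, pseudocount, control)$summary
  out <- data.frame(lfc,
                    intra_fc_spread = pw$intra_fc_spread,
                    inter_fc_mean = pw$inter_fc_mean,
                    p = tst$p, padj = bh_adjust(tst$p),
                    stringsAsFactors = FALSE)
  out$selected <- out$feature %in% select_de(out, lfc_threshold, alpha)
  out
}
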