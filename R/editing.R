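# A-to-I RNA editing: per-site levels, coverage-weighted editing indices
# (Alu / recoding), site filters, and per-site differential editing with
# BH control.

#' Per-site editing level
#'
#' The fraction of reads supporting the edited base, `edited / total`;
#' undefined (`NA`) at zero coverage. Vectorized.
#'
#' @param edited G-supporting read counts (nonnegative).
#' @param total A+G read counts (`edited <= total`).
#' @return Numeric vector of levels in `[0,1]`, `NA` where `total == 0`.
#' @export
editing_level <- function(edited, total) {
  if (any(edited < 0 | total < 0)) .stopf("editing counts must be nonnegative")
  if (any(edited > total)) .stopf("edited exceeds total")
  ifelse(total > 0, edited / total, NA_real_)
}

#' Editing index for one sample (AEI / REI)
#'
#' The coverage-weighted average editing level over all covered sites of a
#' class: `sum(edited) / sum(total)`. Over Alu-class sites this is the Alu
#' Editing Index (AEI); over recoding-class sites, the Recoding Editing
#' Index (REI). An unweighted mean of per-site levels is available as a
#' sensitivity mode.
#'
#' @param table an [editing_site_table].
#' @param sample sample name.
#' @param site_class `"alu"` or `"recoding"`.
#' @param weighting `"coverage"` (default, pooled ratio) or `"unweighted"`
#'   (mean of per-site levels).
#' @return A one-row data.frame: `sample`, `index_class` (AEI/REI),
#'   `value`, `n_sites_used`. `value` is `NA` with a warning when no site
#'   of the class is covered.
#' @export
editing_index <- function(table, sample, site_class = c("alu", "recoding"),
                          weighting = c("coverage", "unweighted")) {
  site_class <- match.arg(site_class)
  weighting <- match.arg(weighting)
  if (!sample %in% colnames(table$edited))
    .stopf("unknown sample '%s'", sample)
  sel <- table$sites$site_class == site_class
  e <- table$edited[sel, sample]
  t <- table$total[sel, sample]
  covered <- t > 0
  cls <- if (site_class == "alu") "AEI" else "REI"
  if (!any(covered)) {
    .warnf("no covered %s site for sample '%s'", site_class, sample)
    return(data.frame(sample = sample, index_class = cls, value = NA_real_,
                      n_sites_used = 0L, stringsAsFactors = FALSE))
  }
  value <- if (weighting == "coverage") sum(e[covered]) / sum(t[covered])
           else mean(e[covered] / t[covered])
  data.frame(sample = sample, index_class = cls, value = value,
             n_sites_used = sum(covered), stringsAsFactors = FALSE)
}

#' Editing indices for all samples
#'
#' @inheritParams editing_index
#' @return A data.frame with one row per sample (columns as in
#'   [editing_index()]).
#' @export
editing_index_all <- function(table, site_class = c("alu", "recoding"),
                              weighting = c("coverage", "unweighted")) {
  site_class <- match.arg(site_class); weighting <- match.arg(weighting)
  do.call(rbind, lapply(colnames(table$edited), function(s)
    editing_index(table, s, site_class, weighting)))
}

#' Filter recoding sites for differential testing
#'
#' A site is retained when (i) it is covered (`total > 0`) in at least
#' `min_samples_per_group` samples of each group, and (ii) the median of
#' its defined per-sample levels, all samples pooled, is strictly greater
#' than `min_median`.
#'
#' @param table an [editing_site_table] with group labels.
#' @param min_samples_per_group coverage floor per group (default 3).
#' @param min_median pooled median editing level floor (default 0.1,
#'   strict).
#' @param groups optional group vector overriding `table$groups`.
#' @return A data.frame, one row per site: `site` (row index), `retained`,
#'   `reason` (`"pass"`, `"coverage"`, `"low_median"`, or both),
#'   `n_covered_ctrl`, `n_covered_case`, `median_level`.
#' @export
filter_recoding_sites <- function(table, min_samples_per_group = 3L,
                                  min_median = 0.1, groups = NULL) {
  groups <- groups %||% table$groups
  if (is.null(groups)) .stopf("group labels required")
  g <- .check_groups(groups, colnames(table$edited))
  lv <- .group_levels(g)
  covered <- table$total > 0
  n_ctrl <- rowSums(covered[, g == lv[1L], drop = FALSE])
  n_case <- rowSums(covered[, g == lv[2L], drop = FALSE])
  levels <- editing_level(table$edited, table$total)
  med <- apply(levels, 1L, median, na.rm = TRUE)
  cov_ok <- n_ctrl >= min_samples_per_group & n_case >= min_samples_per_group
  med_ok <- !is.na(med) & med > min_median
  reason <- vapply(seq_len(nrow(table$sites)), function(i) {
    r <- c(if (!cov_ok[i]) "coverage", if (!med_ok[i]) "low_median")
    if (length(r)) paste(r, collapse = ",") else "pass"
  }, "")
  data.frame(site = seq_len(nrow(table$sites)), retained = cov_ok & med_ok,
             reason = reason, n_covered_ctrl = n_ctrl, n_covered_case = n_case,
             median_level = med, row.names = NULL, stringsAsFactors = FALSE)
}

#' Control-minus-case editing difference
#'
#' Sign convention is control minus case, so a loss of editing in disease
#' yields a positive difference.
#'
#' @param mean_ctrl,mean_case group mean editing levels in `[0,1]`.
#' @return `mean_ctrl - mean_case` (vectorized).
#' @export
edit_difference <- function(mean_ctrl, mean_case) {
  if (any(mean_ctrl < 0 | mean_ctrl > 1 | mean_case < 0 | mean_case > 1,
          na.rm = TRUE))
    .stopf("mean editing levels must lie in [0,1]")
  mean_ctrl - mean_case
}

#' Per-site differential editing
#'
#' Applies the recoding-site filters, then per retained site a Welch
#' two-tailed t-test on per-sample editing levels between groups, BH
#' adjustment across retained sites, and significance at `padj <= fdr`
#' (inclusive). Group means are unweighted means of per-sample levels; the
#' reported effect is the control-minus-case difference.
#'
#' @param table an [editing_site_table] with group labels.
#' @param fdr FDR level (default 0.1).
#' @param min_samples_per_group,min_median site filters (see
#'   [filter_recoding_sites()]).
#' @param groups optional group vector overriding `table$groups`.
#' @param site_class restrict to a class (default `"recoding"`).
#' @return A data.frame, one row per tested site: site annotation columns,
#'   `mean_ctrl`, `mean_case`, `edit_difference`, `p`, `padj`,
#'   `significant`, `flag`. Retained sites with fewer than 2 defined
#'   levels in a group are excluded and reported via attribute
#'   `"excluded"`.
#' @examples
#' sim <- gen_editing_pileups(cbind(c(0.9, 0.2), c(0.6, 0.2)),
#'                            concentration = 200, coverage = 500,
#'                            n_per_group = 6, seed = 3)
#' differential_editing(sim$table)
#' @export
differential_editing <- function(table, fdr = 0.1, min_samples_per_group = 3L,
                                 min_median = 0.1, groups = NULL,
                                 site_class = "recoding") {
  groups <- groups %||% table$groups
  g <- .check_groups(groups, colnames(table$edited))
  lv <- .group_levels(g)
  flt <- filter_recoding_sites(table, min_samples_per_group, min_median,
                               groups = groups)
  keep <- which(flt$retained & table$sites$site_class == site_class)
  levels <- editing_level(table$edited, table$total)
  rows <- list(); excluded <- integer(0)
  for (i in keep) {
    x <- levels[i, g == lv[1L]]; y <- levels[i, g == lv[2L]]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2L || length(y) < 2L) {
      excluded <- c(excluded, i)
      next
    }
    wt <- .welch_p(x, y)
    rows[[length(rows) + 1L]] <-
      cbind(table$sites[i, , drop = FALSE],
            data.frame(mean_ctrl = mean(x), mean_case = mean(y),
                       edit_difference = edit_difference(mean(x), mean(y)),
                       p = wt$p, flag = wt$flag, stringsAsFactors = FALSE))
  }
  if (length(excluded))
    .warnf("%d retained site(s) excluded: fewer than 2 defined levels in a group",
           length(excluded))
  if (!length(rows)) {
    out <- data.frame()
  } else {
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out$padj <- bh_adjust(out$p)
    out$significant <- out$padj <= fdr
  }
  attr(out, "excluded") <- excluded
  attr(out, "filter") <- flt
  out
}

#' Group comparison of per-sample editing indices
#'
#' Welch two-tailed t-test of each index class (AEI, REI) between groups,
#' BH-adjusted across the tested classes, plus box-plot summaries with
#' whiskers at `Q75 + 1.5 * IQR` and `Q25 - 1.5 * IQR`; values outside the
#' whiskers are listed as outliers.
#'
#' @param indices data.frame with columns `sample`, `index_class`, `value`
#'   (e.g. rbind of [editing_index_all()] for both classes).
#' @param groups named group vector.
#' @return A list with `tests` (data.frame `index_class`, `mean_ctrl`,
#'   `mean_case`, `difference`, `p`, `padj`) and `boxstats` (data.frame per
#'   index class and group: quartiles, whiskers, outliers as a
#'   comma-separated string).
#' @export
compare_group_indices <- function(indices, groups) {
  g <- .check_groups(groups, unique(indices$sample))
  lv <- .group_levels(g)
  classes <- unique(indices$index_class)
  tests <- list(); box <- list()
  for (cl in classes) {
    d <- indices[indices$index_class == cl & !is.na(indices$value), ]
    gi <- g[d$sample]
    x <- d$value[gi == lv[1L]]; y <- d$value[gi == lv[2L]]
    wt <- .welch_p(x, y)
    tests[[cl]] <- data.frame(index_class = cl, mean_ctrl = mean(x),
                              mean_case = mean(y),
                              difference = mean(x) - mean(y),
                              p = wt$p, stringsAsFactors = FALSE)
    for (grp in lv) {
      v <- d$value[gi == grp]
      box[[paste(cl, grp)]] <- cbind(index_class = cl, group = grp,
                                     boxplot_stats(v))
    }
  }
  tests <- do.call(rbind, tests)
  tests$padj <- bh_adjust(tests$p)
  rownames(tests) <- NULL
  list(tests = tests, boxstats = do.call(rbind, box))
}

#' Box-plot summary with fixed-formula whiskers
#'
#' Quartiles by linear interpolation (type 7); whiskers at
#' `Q75 + 1.5 * IQR` (upper) and `Q25 - 1.5 * IQR` (lower) where
#' `IQR = Q75 - Q25`; observations outside the whiskers are outliers.
#'
#' @param x numeric vector.
#' @return A one-row data.frame: `q25`, `median`, `q75`, `lower_whisker`,
#'   `upper_whisker`, `n_outliers`, `outliers` (comma-separated).
#' @export
boxplot_stats <- function(x) {
  x <- x[is.finite(x)]
  q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3L] - q[1L]
  up <- q[3L] + 1.5 * iqr
  lo <- q[1L] - 1.5 * iqr
  out <- x[x > up | x < lo]
  data.frame(q25 = q[1L], median = q[2L], q75 = q[3L],
             lower_whisker = lo, upper_whisker = up,
             n_outliers = length(out),
             outliers = paste(out, collapse = ","),
             stringsAsFactors = FALSE)
}
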