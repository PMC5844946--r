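# editing levels, AEI/REI, site filters, differential editing, index tests

test_that("editing level is the edited fraction, undefined at zero coverage", {
  expect_equal(editing_level(5, 10), 0.5)
  expect_equal(editing_level(0, 10), 0)
  expect_true(is.na(editing_level(0, 0)))
  expect_equal(editing_level(c(5, 0, 0), c(10, 10, 0)), c(0.5, 0, NA))
  expect_error(editing_level(7, 5), "exceeds")
  expect_error(editing_level(-1, 5), "nonnegative")
})

test_that("editing index is the coverage-weighted pooled ratio", {
  ed <- matrix(c(3L, 1L, 3L), 3, 1, dimnames = list(NULL, "s1"))
  tot <- matrix(c(10L, 10L, 10L), 3, 1, dimnames = list(NULL, "s1"))
  one <- toy_pileup(ed[1, , drop = FALSE], tot[1, , drop = FALSE],
                    site_class = "alu")
  idx1 <- editing_index(one, "s1", "alu")
  expect_equal(idx1$value, 0.3)           # single site: index = its level
  expect_identical(idx1$index_class, "AEI")
  two <- toy_pileup(ed[2:3, , drop = FALSE], tot[2:3, , drop = FALSE])
  idx2 <- editing_index(two, "s1", "recoding")
  expect_equal(idx2$value, 4 / 20)        # hand summation oracle
  expect_identical(idx2$index_class, "REI")
  full <- toy_pileup(tot, tot)
  expect_equal(editing_index(full, "s1", "recoding")$value, 1)
})

test_that("index is invariant to uniform coverage doubling and bounded by site levels", {
  set.seed(201)
  tot <- matrix(sample(5:60, 20, replace = TRUE), 10, 2,
                dimnames = list(NULL, c("s1", "s2")))
  ed <- matrix(rbinom(20, as.vector(tot), 0.4), 10, 2,
               dimnames = dimnames(tot))
  tab <- toy_pileup(ed, tot)
  tab2 <- toy_pileup(2L * ed, 2L * tot)
  for (s in c("s1", "s2")) {
    v1 <- editing_index(tab, s, "recoding")$value
    v2 <- editing_index(tab2, s, "recoding")$value
    expect_equal(v1, v2)
    lev <- ed[, s] / tot[, s]
    expect_gte(v1, min(lev)); expect_lte(v1, max(lev))
  }
})

test_that("index is missing with a warning when no site is covered", {
  tab <- toy_pileup(matrix(0L, 2, 1, dimnames = list(NULL, "s1")),
                    matrix(0L, 2, 1, dimnames = list(NULL, "s1")))
  expect_warning(idx <- editing_index(tab, "s1", "recoding"), "no covered")
  expect_true(is.na(idx$value))
  expect_identical(idx$n_sites_used, 0L)
})

test_that("site filters reproduce hand-evaluated keep/drop decisions on a 10-site toy", {
  # 4 control + 6 case samples
  g <- setNames(rep(c("control", "case"), c(4, 6)), paste0("s", 1:10))
  tot <- matrix(20L, 10, 10, dimnames = list(NULL, names(g)))
  ed <- matrix(10L, 10, 10, dimnames = dimnames(tot))   # level 0.5 baseline
  # site 1: covered in only 2 control samples -> coverage drop
  tot[1, 1:2] <- 0L; ed[1, 1:2] <- 0L
  # site 2: covered in only 2 case samples -> coverage drop
  tot[2, 7:10] <- 0L; ed[2, 7:10] <- 0L
  # site 3: pooled median level 0.05 -> low_median drop
  ed[3, ] <- 1L
  # site 4: median exactly 0.1 -> strict inequality drops it
  ed[4, ] <- 2L
  # site 5: median just above 0.1 -> retained
  ed[5, ] <- 3L
  # site 6: covered in exactly 3 per group -> retained
  tot[6, c(1, 7, 8)] <- 0L; ed[6, c(1, 7, 8)] <- 0L
  # site 7: level high but zero coverage everywhere in controls
  tot[7, 1:4] <- 0L; ed[7, 1:4] <- 0L
  tab <- toy_pileup(ed, tot, groups = g)
  flt <- filter_recoding_sites(tab, min_samples_per_group = 3, min_median = 0.1)
  expect_identical(flt$retained,
                   c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE,
                     TRUE, TRUE, TRUE))
  expect_match(flt$reason[1], "coverage")
  expect_match(flt$reason[3], "low_median")
  expect_match(flt$reason[4], "low_median")
  expect_match(flt$reason[7], "coverage")
  expect_equal(flt$median_level[5], 0.15)
  expect_identical(flt$n_covered_ctrl[1], 2)
})

test_that("edit difference follows the control-minus-case convention", {
  expect_equal(edit_difference(0.972, 0.918), 0.054)
  expect_equal(edit_difference(0.524, 0.290), 0.234)
  expect_equal(edit_difference(0.3, 0.3), 0)
  expect_equal(edit_difference(0.2, 0.5), -edit_difference(0.5, 0.2))
  expect_error(edit_difference(1.2, 0.5), "\\[0,1\\]")
})

test_that("differential editing reproduces a manual 3v3 Welch test", {
  g <- setNames(rep(c("control", "case"), each = 3), paste0("s", 1:6))
  tot <- matrix(100L, 1, 6, dimnames = list(NULL, names(g)))
  ed <- matrix(c(90L, 85L, 95L, 60L, 55L, 65L), 1, 6,
               dimnames = dimnames(tot))
  tab <- toy_pileup(ed, tot, groups = g)
  res <- differential_editing(tab, min_samples_per_group = 3)
  x <- c(0.90, 0.85, 0.95); y <- c(0.60, 0.55, 0.65)
  se2 <- var(x) / 3 + var(y) / 3
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((var(x) / 3)^2 / 2 + (var(y) / 3)^2 / 2)
  expect_equal(res$p, 2 * pt(-abs(tstat), df), tolerance = 1e-12)
  expect_equal(res$mean_ctrl, 0.9)
  expect_equal(res$mean_case, 0.6)
  expect_equal(res$edit_difference, 0.3)
  expect_true(res$significant)
})

test_that("identical group levels give zero difference and p = 1", {
  g <- setNames(rep(c("control", "case"), each = 3), paste0("s", 1:6))
  tot <- matrix(10L, 1, 6, dimnames = list(NULL, names(g)))
  ed <- matrix(5L, 1, 6, dimnames = dimnames(tot))
  res <- differential_editing(toy_pileup(ed, tot, groups = g),
                              min_samples_per_group = 3)
  expect_equal(res$edit_difference, 0)
  expect_equal(res$p, 1)
  expect_identical(res$flag, "degenerate_equal")
})

test_that("differential editing recovers generator truth near Table-5-like levels", {
  gm <- cbind(c(0.601, 0.972), c(0.393, 0.918))
  sim <- gen_editing_pileups(gm, concentration = 500, coverage = 1000,
                             n_per_group = 5, seed = 211)
  res <- differential_editing(sim$table)
  expect_equal(nrow(res), 2L)
  expect_lt(abs(res$edit_difference[1] - 0.208), 0.05)
  expect_lt(abs(res$edit_difference[2] - 0.054), 0.05)
})

test_that("null editing data keep the significant fraction near the FDR level", {
  gm <- matrix(0.4, 60, 2)
  hits <- 0; total <- 0
  for (s in 1:5) {
    sim <- gen_editing_pileups(gm, concentration = 30, coverage = 80,
                               n_per_group = 5, seed = 220 + s)
    res <- differential_editing(sim$table)
    hits <- hits + sum(res$significant)
    total <- total + nrow(res)
  }
  # BH keeps the expected significant fraction at or below the FDR level
  # under the null; allow binomial noise on 300 sites
  expect_lte(hits / total, 0.1 + 3 * sqrt(0.1 * 0.9 / total))
})

test_that("group index comparison: whisker formula and power on REI decrease", {
  # whiskers of (1..9, 100): type-7 quartiles and the stated formula
  bs <- boxplot_stats(c(1:9, 100))
  q <- quantile(c(1:9, 100), c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  expect_equal(bs$upper_whisker, q[2] + 1.5 * iqr)
  expect_equal(bs$lower_whisker, q[1] - 1.5 * iqr)
  expect_identical(bs$n_outliers, 1L)
  expect_identical(bs$outliers, "100")
  # REI group means 0.5 vs 0.3, tight concentration: significant at 0.05
  gm <- matrix(c(rep(0.5, 20), rep(0.3, 20)), 20, 2)
  sim <- gen_editing_pileups(gm, concentration = 400, coverage = 500,
                             n_per_group = 5, seed = 231)
  idx <- editing_index_all(sim$table, "recoding")
  cmp <- compare_group_indices(idx, sim$table$groups)
  expect_lt(cmp$tests$p[1], 0.05)
  expect_gt(cmp$tests$difference[1], 0)        # control minus case
  # identical groups: p = 1 convention
  flat_tot <- matrix(10L, 2, 6, dimnames = list(NULL, paste0("s", 1:6)))
  flat_ed <- matrix(5L, 2, 6, dimnames = dimnames(flat_tot))
  gflat <- setNames(rep(c("control", "case"), each = 3), paste0("s", 1:6))
  idx2 <- editing_index_all(toy_pileup(flat_ed, flat_tot), "recoding")
  cmp2 <- compare_group_indices(idx2, gflat)
  expect_equal(cmp2$tests$p, 1)
  expect_equal(cmp2$tests$difference, 0)
})
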