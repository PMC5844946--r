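# geNorm M, NormFinder-style stability, consensus selection, ddCt

# long Ct table from a sample x gene matrix, single replicate
ct_from_wide <- function(wide, groups) {
  do.call(rbind, lapply(rownames(wide), function(s)
    data.frame(sample = s, group = groups[[s]], gene = colnames(wide),
               replicate = 1L, ct = wide[s, ], row.names = NULL,
               stringsAsFactors = FALSE)))
}

test_that("geNorm M matches a hand computation on a 3-gene, 4-sample toy", {
  wide <- rbind(s1 = c(A = 20.0, B = 22.0, C = 25.0),
                s2 = c(A = 20.5, B = 22.4, C = 26.0),
                s3 = c(A = 19.8, B = 21.9, C = 24.2),
                s4 = c(A = 20.2, B = 22.3, C = 25.5))
  g <- c(s1 = "control", s2 = "control", s3 = "case", s4 = "case")
  ct <- ct_from_wide(wide, g)
  gm <- genorm_m(ct, c("A", "B", "C"))
  v_ab <- sd(wide[, "A"] - wide[, "B"])
  v_ac <- sd(wide[, "A"] - wide[, "C"])
  v_bc <- sd(wide[, "B"] - wide[, "C"])
  expect_equal(unname(gm$m["A"]), mean(c(v_ab, v_ac)), tolerance = 1e-12)
  expect_equal(unname(gm$m["B"]), mean(c(v_ab, v_bc)), tolerance = 1e-12)
  expect_equal(unname(gm$m["C"]), mean(c(v_ac, v_bc)), tolerance = 1e-12)
  expect_identical(gm$exclusion_order, "C")     # C is the noisy one
})

test_that("geNorm M agrees with the brute-force pairwise-SD oracle on random tables", {
  set.seed(241)
  for (i in 1:25) {
    n_g <- sample(3:6, 1); n_s <- sample(4:10, 1)
    wide <- matrix(rnorm(n_s * n_g, 22, 1.5), n_s, n_g,
                   dimnames = list(paste0("s", 1:n_s), paste0("g", 1:n_g)))
    groups <- setNames(rep(c("control", "case"), length.out = n_s),
                       rownames(wide))
    ct <- ct_from_wide(wide, groups)
    gm <- genorm_m(ct, colnames(wide))
    expect_equal(gm$m, oracle_genorm_m(wide, colnames(wide)),
                 tolerance = 1e-10)
  }
})

test_that("pairwise V and M are invariant to constant per-gene Ct shifts", {
  sim <- gen_ct_table("T", c(H1 = 0.1, H2 = 0.2, H3 = 0.4), c(T = 1),
                      seed = 251)
  m1 <- genorm_m(sim$ct, sim$housekeepers)$m
  shifted <- sim$ct
  shifted$ct[shifted$gene == "H2"] <- shifted$ct[shifted$gene == "H2"] + 3
  m2 <- genorm_m(shifted, sim$housekeepers)$m
  expect_equal(m1, m2, tolerance = 1e-12)
  # identical Ct vectors (duplicated gene) have pairwise V = 0
  dup <- sim$ct
  extra <- dup[dup$gene == "H1", ]; extra$gene <- "H1b"
  dup <- rbind(dup, extra)
  gmd <- genorm_m(dup, c("H1", "H1b", "H2", "H3"))
  expect_lt(sd(dup$ct[dup$gene == "H1"] - dup$ct[dup$gene == "H1b"]), 1e-12)
  expect_lt(abs(unname(gmd$m["H1"] - gmd$m["H1b"])), 1e-12)
})

test_that("geNorm errors when a candidate is missing in a sample", {
  sim <- gen_ct_table("T", c(H1 = 0, H2 = 0.1, H3 = 0.2), c(T = 1),
                      seed = 261)
  ct <- sim$ct[!(sim$ct$sample == "ctrl-1" & sim$ct$gene == "H2"), ]
  expect_error(genorm_m(ct, sim$housekeepers), "H2")
  expect_error(genorm_m(sim$ct, c("H1", "H2")), ">= 3")
})

test_that("NormFinder-style stability ranks constructed genes correctly", {
  set.seed(271)
  samples <- paste0("s", 1:10)
  groups <- setNames(rep(c("control", "case"), each = 5), samples)
  wide <- cbind(stable = rep(20, 10),
                noisy = 20 + rnorm(10, 0, 0.8),
                biased = rep(20, 10) + 0.02 * rnorm(10))
  rownames(wide) <- samples
  # +2-cycle shift in one group only: inter-group bias dominates
  wide[groups == "case", "biased"] <- wide[groups == "case", "biased"] + 2
  ct <- ct_from_wide(wide, groups)
  nf <- normfinder_stability(ct, colnames(wide), groups)
  expect_identical(names(which.min(nf$stability)), "stable")
  expect_identical(names(which.max(nf$stability)), "biased")
  # permuting sample order leaves stabilities unchanged
  perm <- ct[sample(nrow(ct)), ]
  nf2 <- normfinder_stability(perm, colnames(wide), groups)
  expect_equal(nf$stability, nf2$stability[names(nf$stability)],
               tolerance = 1e-12)
})

test_that("consensus housekeeper selection follows both rankings, geNorm breaking ties", {
  gn <- list(ranking = c("A", "B", "C", "D", "E"))
  nf <- list(ranking = c("A", "B", "C", "D", "E"))
  expect_identical(select_housekeepers(gn, nf, 3), c("A", "B", "C"))
  # disagreement: only A and C are in both top-3; geNorm fills with B
  nf2 <- list(ranking = c("C", "E", "A", "B", "D"))
  expect_identical(select_housekeepers(gn, nf2, 3), c("A", "C", "B"))
  expect_identical(select_housekeepers(gn, nf, 5), c("A", "B", "C", "D", "E"))
  expect_error(select_housekeepers(gn, nf, 6), "exceeds")
  # 5 candidates, k = 3 on simulated data returns a size-3 set
  sim <- gen_ct_table("T", c(H1 = 0.05, H2 = 0.1, H3 = 0.3, H4 = 0.8,
                             H5 = 1.5), c(T = 1), seed = 281)
  rep_ <- stability_report(sim$ct, sim$housekeepers, k = 3)
  expect_length(rep_$selected, 3L)
  expect_true(all(rep_$selected %in% sim$housekeepers))
  # the grossly unstable candidates should not be selected
  expect_false(any(c("H4", "H5") %in% rep_$selected))
})

test_that("ddCt identities: calibrator zero-mean, +1-cycle shift, flat table", {
  g <- c(s1 = "control", s2 = "control", s3 = "case", s4 = "case")
  wide <- rbind(s1 = c(T = 24, H1 = 20, H2 = 22, H3 = 21),
                s2 = c(T = 25, H1 = 21, H2 = 23, H3 = 22),
                s3 = c(T = 23.5, H1 = 20.5, H2 = 22.5, H3 = 21.5),
                s4 = c(T = 24.5, H1 = 21.5, H2 = 23.5, H3 = 22.5))
  ct <- ct_from_wide(wide, g)
  q <- ddct_quantify(ct, "T", c("H1", "H2", "H3"))
  expect_equal(q$summary$mean_log2_rel[q$summary$group == "control"], 0,
               tolerance = 1e-12)
  # target exactly 1 cycle lower in each case sample, housekeepers aligned:
  # dCt(control) = 3 each, dCt(case) = 2 each -> case log2_rel = +1 exactly
  expect_equal(q$per_sample$log2_rel[q$per_sample$group == "case"], c(1, 1),
               tolerance = 1e-12)
  # all Cts identical across samples: log2_rel 0 everywhere, p = 1
  flat <- ct_from_wide(matrix(22, 4, 4, dimnames = dimnames(wide)), g)
  qf <- ddct_quantify(flat, "T", c("H1", "H2", "H3"))
  expect_true(all(abs(qf$per_sample$log2_rel) < 1e-12))
  expect_equal(qf$p, 1)
})

test_that("log2_rel is invariant to constant housekeeper shifts", {
  sim <- gen_ct_table("T", c(H1 = 0, H2 = 0, H3 = 0), c(T = 1.5),
                      seed = 291)
  q1 <- ddct_quantify(sim$ct, "T", sim$housekeepers)
  shifted <- sim$ct
  hk <- shifted$gene %in% sim$housekeepers
  shifted$ct[hk] <- shifted$ct[hk] + 2.5
  q2 <- ddct_quantify(shifted, "T", sim$housekeepers)
  expect_equal(q1$per_sample$log2_rel, q2$per_sample$log2_rel,
               tolerance = 1e-12)
})

test_that("simulated group effects are recovered within 3 standard errors", {
  for (eff in c(1, -1.5)) {
    sim <- gen_ct_table("T", c(H1 = 0.05, H2 = 0.05, H3 = 0.05),
                        c(T = eff), replicate_sd = 0.1, n_per_group = 6,
                        seed = 300 + round(10 * abs(eff)))
    q <- ddct_quantify(sim$ct, "T", sim$housekeepers)
    est <- q$summary$mean_log2_rel[q$summary$group == "case"]
    se <- 3 * 0.1 / sqrt(6)
    expect_lt(abs(est - eff), 3 * se + 0.1)
  }
})

test_that("samples missing a gene are excluded with a warning", {
  sim <- gen_ct_table("T", c(H1 = 0, H2 = 0, H3 = 0), c(T = 1), seed = 311)
  ct <- sim$ct[!(sim$ct$sample == "case-2" & sim$ct$gene == "T"), ]
  expect_warning(q <- ddct_quantify(ct, "T", sim$housekeepers), "case-2")
  expect_false("case-2" %in% q$per_sample$sample)
  expect_error(ddct_quantify(sim$ct, "H1", sim$housekeepers), "housekeeper")
})
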