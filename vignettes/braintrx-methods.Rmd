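---
title: "Methods: small-RNA quantification, count-based DE, RNA-editing indices and ddCt analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-RNA quantification, count-based DE, RNA-editing indices and ddCt analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(braintrx)
```

`braintrx` re-implements, as tested and reusable components, the bespoke
computational stages of a bulk brain transcriptome analysis of
neurodegenerative disease tissue: exact-overlap small-RNA quantification, a
count-based differential-expression (DE) procedure, A-to-I RNA-editing
indices with per-site differential editing, and RT-qPCR relative
quantification with reference-gene stability selection. This vignette
explains each model, its assumptions, the tunable parameters and their
defaults, the synthetic-data generators used for calibration, and the
numerical conventions.

## Small-RNA read assignment

Mature miRNAs are 18–24 nt; sequencing reads (50 nt here) therefore run
through the insert into the 3' adapter. Processing is in three steps.

**Adapter trimming.** `trim_adapter()` truncates a read at the first exact
occurrence of the adapter's leading 8 nt (`seed_len`). An exact seed-prefix
match is used because at 8 nt the chance of a spurious hit inside a random
insert is 4^-8 ≈ 1.5e-5 per position, negligible at these insert lengths,
and it keeps the trimmer a pure function of the sequence. Reads without a
hit are kept and flagged; inserts shorter than 17 nt are discarded — they
can never reach the minimum assignment overlap.

**Assignment.** `assign_read()` scores every miRNA at every ungapped
offset. The score of an offset is the length of the overlap (the
intersection of read and miRNA spans), a candidate requires overlap ≥ 17 nt
with **zero** mismatches inside it, and the read is assigned to the unique
maximal-scoring miRNA. Two choices deserve emphasis:

* *Overhang is ignored, not penalized.* Bases of the read that extend past
  either miRNA terminus (isomiR-style untemplated additions, residual
  adapter) are excluded from the overlap rather than counted as
  mismatches.
* *Ambiguity is not resolved by fiat.* When two or more distinct miRNAs
  tie at the maximal score — typical for family members that differ at one
  position outside the read — the read is reported `unassigned_ambiguous`
  and never counted. This keeps the count matrix's column sums equal to
  the number of assigned reads and avoids double counting; the
  alternative (fractional or multi-counting) would silently inflate family
  counts.
* *No reverse-complement search.* Small-RNA library protocols are
  stranded; the search is over the given orientation only.

The implementation is checked against an exhaustive character-by-character
brute-force scorer on a thousand randomized read/reference instances, and
assignment must be invariant to reference ordering.

**Expression filter.** `filter_expressed()` retains a miRNA when some
sample reaches 10 reads (`min_count`, default mode `max_per_sample`). The
two published phrasings of this floor ("at least 10" and "higher than 10")
disagree at the boundary, so a `strict_gt` mode and a `total` mode (floor
applied to the row total) are provided; the default takes the inclusive
reading and no intent is guessed.

## Count-based differential expression

The DE procedure deliberately avoids a mean–variance model: it is an
upper-quartile-normalized, log-scale Welch t-test with BH correction,
i.e. the simplest defensible test for 5–6 samples per group.

**Upper-quartile normalization.** `uq_normalize()` computes each sample's
size factor as the 75th percentile of its counts over features that are
nonzero in at least one sample, divides by it, and rescales all samples by
the geometric mean of the size factors so the matrix keeps its overall
scale. Quartiles use linear interpolation (R's type 7), fixed for
reproducibility. A sample whose qualifying counts are all zero is an
error, not a silent NaN.

**Fold change and test.** `log2_fold_change()` reports
`log2((mean_case + c)/(mean_ctrl + c))` with pseudocount `c = 1` by
default — zeros are routine in miRNA counts at these depths. The test
(`de_test()`, mode `log_expression`) is a Welch two-tailed t on
`log2(normalized + c)`; Welch rather than pooled variance because nothing
justifies equal group variances at n = 5. The published description of the
method — comparing fold changes "intra- and inter-conditions" —
under-determines the statistic, so the literal reading is also
implemented: mode `fc_contrast` tests the inter-condition pairwise log2
ratios against the pooled intra-condition ratios
(`choose(n1,2) + choose(n2,2)` intra vs `n1*n2` inter values per feature).
The pairwise sets are always computed and reported as diagnostics
(`intra_fc_spread`, `inter_fc_mean`) whichever mode runs. `fc_contrast`
treats dependent pairwise ratios as if exchangeable and is provided for
sensitivity, not as the default.

**Degenerate features.** Zero variance in both groups with equal means
gives p = 1 by convention; with unequal means the p-value is reported as
the smallest representable double and flagged — both cases are logged in
the `flag` column rather than erroring mid-matrix.

**Selection.** `select_de()` applies |log2FC| > 1 and BH-adjusted
p < 0.05, both strict, matching the published rule's wording.

**Calibration.** On simulated nulls (2,000 negative-binomial features,
5 vs 5) the raw p-values are close to uniform; the suite asserts the
fraction below 0.05 inside the exact binomial 99% interval. The Welch t on
log counts is known to run mildly conservative for over-dispersed counts
at n = 5 (observed type-I ≈ 0.034–0.045 across seeds) — a property of the
test itself, stated here so that passing calibration is not over-read.
Power checks use high means (1,000) and low dispersion (0.01), where the
sampling SD of a log2FC estimate, ≈ sqrt(2(1/μ + φ)/n)/ln 2 ≈ 0.10, sits
well inside the ±0.3 recovery band; at dispersion ≥ 0.05 that SD is ≈ 0.2
and a ±0.3 per-feature guarantee is statistically meaningless, which is
why the recovery conditions are what they are.

## A-to-I RNA editing

Editing is quantified from per-site pileup counts: `edited` (G-supporting
reads) and `total` (A+G) per site and sample; the level is `edited/total`,
undefined at zero coverage.

**Indices.** `editing_index()` pools sites of a class by coverage:
`Σ edited / Σ total` over covered sites — the weighted-average form of the
Alu Editing Index (AEI), and, restricted to recoding sites, the Recoding
Editing Index (REI). Coverage weighting follows the established
index methodology; an unweighted per-site mean is available
(`weighting = "unweighted"`) for sensitivity. The index is invariant to
uniform coverage doubling and always lies between the extreme contributing
site levels. Genome-wide Alu aggregation from alignments is out of scope;
the index is computed over whatever site list is supplied, which is the
desk-scale analogue.

**Site filters.** A recoding site enters testing only if covered in at
least 3 samples *per group* and its median level — over all defined
per-sample levels, groups pooled, strict inequality — exceeds 0.1. The
pooled (rather than per-group) median is a documented choice; the source
text does not specify grouping.

**Differential editing.** Per retained site, a Welch two-tailed t on the
per-sample levels (raw proportions — an arcsine-sqrt option was considered
and rejected as the default because the published analysis states a plain
t-test), BH across retained sites, significance at padj ≤ 0.1 inclusive.
Group means are unweighted means of per-sample levels — matching how
per-group "mean editing" is conventionally tabulated — and the reported
effect is `mean_ctrl − mean_case`, so an editing *loss* in disease is
positive. Box-plot summaries for index comparisons place whiskers at
Q75 + 1.5·IQR and Q25 − 1.5·IQR (the lower-whisker formula is the obvious
correction of a sign typo in the source figure caption).

## RT-qPCR: stability selection and ΔΔCt

**geNorm M.** For candidates j,k the pairwise variation `V_jk` is the SD
over samples of `Ct_j − Ct_k`; `M_j` is the mean over partners. Constant
per-gene shifts cancel, so M measures co-variation, not absolute level.
Iterative exclusion of the worst gene yields the ranking, ending in an
unresolvable most-stable pair.

**NormFinder-style stability.** Ct values are centered per sample across
the candidate set (removing the shared input/loading component), then per
gene the group-mean deviation `d_ag` and within-group variance `v_ag` of
the centered residuals are combined as
`mean_a sqrt(d_ag² + v_ag/n_a)`. This follows the published model's
intra/inter-group variance decomposition; it is not a bit-compatible port
of the original spreadsheet applet, and ranks are what is consumed
downstream.

**Consensus.** `select_housekeepers()` takes genes in both methods' top-k
first, then fills by geNorm rank — i.e. geNorm breaks all disagreements.
The original analysis does not state its merge rule; this one is fixed and
documented.

**ΔΔCt.** Replicate Cts are averaged per (sample, gene); `ΔCt` subtracts
the arithmetic mean of the selected housekeepers; `ΔΔCt` subtracts the
control-group mean ΔCt (the calibrator); the reported quantity is
`log2_rel = −ΔΔCt`, the log2-scale relative expression (log2 of 2^−ΔΔCt).
The source reports "log2(ΔΔCt)", which read literally is the logarithm of
a signed cycle difference; the only reading consistent with up-regulated
genes plotting positive is −ΔΔCt, which is what is implemented. Two exact
identities follow and are asserted: the control-group mean of `log2_rel`
is 0, and any constant shift of all housekeeper Cts cancels. No
amplification-efficiency correction (Pfaffl) is applied; perfect doubling
per cycle is assumed, as in the ΔΔCt method itself.

## Synthetic data and what it does (not) show

Every pipeline input can be generated with serialized ground truth
(`gen_*` functions), so calibration and power claims are made against
known truth rather than re-derived quantities:

* `gen_mirna_reference()` — random mature sequences (default 20–23 nt,
  minimum 18 so a 17-nt overlap is attainable), plus "family pairs" at
  Hamming distance 1 whose shared ≥ 17-nt block exercises ambiguity
  handling.
* `gen_small_rna_reads()` — reads laid out as insert + 3' adapter +
  random padding to 50 nt; isomiR end-variation as 0–3 nt end trimming
  (extension is not modelled — it would require flanking genomic context);
  optional planted substitutions positioned so that every ≥ 17-nt window
  of the insert is hit, making such reads unassignable by construction
  whenever the insert is ≤ 33 nt.
* `gen_count_matrix()` — negative-binomial counts; feature means
  log-normal (meanlog = log(150), sdlog = 0.8 by default, a realistic
  spread for miRNA libraries of a few million reads), dispersion 0.15 by
  default, per-sample depth factors uniform in 0.7–1.3 to exercise
  upper-quartile normalization, and a chosen fraction of features shifted
  by ±lfc in the second group.
* `gen_editing_pileups()` — per-sample levels Beta(mθ, (1−m)θ) around the
  group mean m with concentration θ, Poisson coverage, binomial edited
  counts, optional coverage dropout to exercise the per-group coverage
  filter.
* `gen_ct_table()` — Ct = gene baseline + shared sample offset +
  housekeeper instability noise − group effect (targets, case group) +
  replicate noise; the intended downstream −ΔΔCt equals the group effect.

These generators emulate the *statistical* structure the analyses assume —
over-dispersed counts, beta-distributed editing levels, additive Ct
noise — and none of the biological structure they do not: no sequence
composition bias, no quality-score realism, no correlated features, no
batch effects, no amplification-efficiency variation. Passing tests
demonstrate that the implementations compute their statistics correctly
and are calibrated under their own model assumptions; they say nothing
about cohort-scale biological findings, which require the original
patient sequencing data.

Problem sizes used in the automated checks (2,000 simulated features at
5 vs 5; ≤ 1,000 assignment instances; 6 vs 6 editing samples at coverage
~1,000; 25–60 sites) were chosen so every claim is testable in seconds
while keeping Monte-Carlo error far from each asserted bound.

## Numerical conventions

* Coordinates are 1-based inclusive internally; BED I/O converts at the
  boundary (`pos = start + 1` on ingest), so printed positions like
  `chr4:158257875` round-trip.
* All quantiles are type 7 (linear interpolation).
* One integer seed drives every generator; identical seed + parameters
  give byte-identical outputs, and CLI runs log the seed and a
  configuration hash.
* Validation errors name the offending row, sample or line; degenerate
  statistics are flagged, not silently clamped.

## Worked example

```{r example}
sim <- gen_count_matrix(500, n_per_group = 5, de_fraction = 0.1, lfc = 2,
                        nb_dispersion = 0.05, base_mean = 400, seed = 7)
res <- run_de(sim$counts, sim$groups)
head(res[order(res$padj), c("feature", "log2fc", "p", "padj", "selected")])
mean(res$selected[sim$truth$is_de])   # recall at these settings
```
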