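---
title: "Methods: signature permutation testing, consensus clustering and SAM-ranked enrichment"
author: "sigperm authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature permutation testing, consensus clustering and SAM-ranked enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigperm)
```

## The scientific question

In chronic myeloid leukemia (CML), progression from chronic phase (CP) to
blast crisis (BC) is accompanied by transcriptional reprogramming of
CD34+CD38+Lin- progenitors. Two recurring questions in cohort studies of
this kind are:

1. Does an *a-priori* gene signature — for example a curated set of 41
   Hedgehog (Hh) pathway genes — separate normal, chronic-phase and
   blast-crisis progenitors better than chance?
2. Does a treatment — for example a SMO antagonist given to xenografted
   mice — repress annotated pathways (cell-cycle regulation, dormancy
   programs) relative to vehicle?

`sigperm` implements both analysis chains end to end, together with the
quantification, filtering, clustering and per-gene statistics around them,
and a synthetic-data generator that plants known structure so every stage
can be validated by parameter recovery, calibration and oracle equivalence.

## Quantification and filtering

Counts enter as a gene-by-sample integer matrix with per-gene exonic
lengths. The stages, each a separate function with the stage recorded on
the result:

* **RPKM** — `rpkm(g,s) = count(g,s) * 1e9 / (length(g) * total(s))`.
  `total(s)` defaults to the column sum of the supplied matrix; the totals
  actually used by an aligner's coverage analysis can differ (all mapped
  reads vs reads in annotated genes), so a user-supplied totals vector
  overrides it.
* **Detectable expression** — keep genes with RPKM strictly above 0.2 in
  strictly more than 75% of samples. Both inequalities are strict by
  design; a weaker "not zero in every sample" mode is available for
  analyses that only need to drop dead rows.
* **Minimum counts** (enrichment chain) — keep genes with at least 10
  reads in one or more samples.
* **Upper-quartile normalization** — each sample divided by the 75th
  percentile of its *nonzero* counts (the standard UQ convention; the
  quartile of all counts would be dominated by zeros in sparse data), then
  rescaled by the geometric mean of those quartiles so the output keeps the
  magnitude of the input. Because of that magnitude-preserving factor,
  rescaling sample depths changes the output only by one global constant —
  the per-sample structure is depth-invariant.
* **log2 median centering** — `log2(rpkm + 0.01)` minus the per-gene
  median, the representation used for clustering and for the signature
  test. The pseudocount (default 0.01, configurable) maps RPKM = 0 to a
  finite value; entries that were exactly zero are additionally flagged in
  a `not_expressed` attribute so display layers can grey them out rather
  than color them as "low".

## The signature permutation test

The core question — "does this signature separate the groups better than a
random gene set of the same size?" — is answered in three steps
(`signature_perm_test()`):

1. **Signature-restricted PCA.** Samples are observations, the signature's
   expressed genes are variables; variables are centered but not rescaled
   (the input is already log2 median-centered per gene, so per-gene scale
   is meaningful and is deliberately retained). The first 3 components are
   kept. A deterministic sign convention (largest-magnitude loading
   positive) makes results reproducible across BLAS implementations.
2. **MANOVA.** A one-way MANOVA of the 3 component scores on the group
   label, summarized by the F approximation of Pillai's trace. Pillai was
   chosen over Wilks/Hotelling for its robustness to covariance
   heterogeneity between groups; with one response it reduces exactly to
   the one-way ANOVA F (a tested degeneracy).
3. **Random gene-set null.** The same PCA + MANOVA statistic is recomputed
   for `n_draws = 5000` gene sets drawn uniformly without replacement from
   the annotated expressed-gene universe, with the same size as the
   expressed signature. The p-value is the upper-tail proportion
   `#{null F >= observed F} / n_draws`, ties counting against the observed
   statistic.

Two conventions deserve a note. First, the tail direction: a literal
"proportion of null statistics the observed value exceeds" would make
strong separation yield a *large* p; the upper-tail rule is the default and
the literal rule is available as `rule = "literal"`, with the choice
recorded in the result's provenance. Second, no add-one correction is
applied by default, matching the plain-proportion definition; the
`(1+k)/(1+n)` corrected mode is available (`add_one = TRUE`) and is the
better choice whenever the p-value feeds downstream inference, since it
cannot return exactly zero. Null draws do not exclude the signature's own
genes by default (`exclude_signature` flips this); with a realistic
universe-to-signature ratio the difference is negligible.

## Clustering

* **Spearman distance** `1 - rho` (average-rank ties) between sample or
  gene profiles, with an explicit error for constant profiles, whose rank
  correlation is undefined.
* **Complete-linkage agglomerative clustering** via `stats::hclust`,
  re-exposed with the merge sequence as explicit triples and Newick export
  (branch lengths from merge heights). The test suite proves equivalence
  to a brute-force cubic-time implementation on random instances up to 10
  leaves.
* **Consensus NMF.** `nmf_brunet()` minimizes the generalized
  Kullback-Leibler divergence with the classic multiplicative updates from
  random uniform starting factors. Numerical conventions: `0*log(0) = 0`;
  entries of `W %*% H` are floored at `1e-12` inside logs and ratios;
  iteration stops at a relative divergence change below `1e-6` (default)
  or 2000 updates. The divergence trace is returned and tested to be
  non-increasing at every update (up to `1e-8` relative floating-point
  slack near convergence).
  `consensus_matrix()` repeats the fit over `n_runs = 200` random restarts
  ("iterations" in the sense of consensus clustering — full restarts, not
  multiplicative-update steps), assigns each sample to its arg-max row of
  `H` (ties to the lowest factor index) and averages the connectivity
  matrices. `rank_survey()` adds a randomized baseline in which every gene
  row is independently permuted, destroying between-sample structure while
  preserving per-gene marginals, surveyed at 25 restarts per rank against
  50 for the data.
* **Rank selection.** The cophenetic correlation coefficient — Pearson
  correlation between consensus distances `1 - C` and the cophenetic
  distances of the average-linkage tree built on them — is computed per
  rank, and `select_rank()` picks the rank at which the curve stops rising
  (the classic "where the cophenetic coefficient begins to fall" rule).
  Taking the plain arg-max instead would be ambiguous on easy data, where
  several ranks can reach exactly 1.

A practical caveat, visible in the tests: even on perfectly block-diagonal
input a small minority of random restarts can converge to a worse local
optimum of the KL objective and merge two blocks. Consensus entries are
therefore near- rather than exactly binary; the consensus partition and
the cophenetic coefficient are robust to this.

## Per-gene and per-assay statistics

* **Mann-Whitney U** (two-sided): exact p by the null distribution of U
  when both groups have at most 8 observations and there are no ties —
  the exact two-sided p is the doubled smaller tail, capped at 1 — and the
  normal approximation with tie correction and continuity correction
  otherwise. The exact/approximate switch is by enumeration feasibility,
  not by a distributional argument.
* **BH adjustment** through `stats::p.adjust`, with the per-gene chain
  (`de_genes()`) selecting at FDR < 0.05 and reporting the log2 ratio of
  group medians (pseudocount 0.01) as the effect size.
* **2x2 factorial synergy test** (`factorial_interaction_test()`): per-gene
  `y ~ A + B + A:B`. The moderated path uses limma's empirical-Bayes
  variance shrinkage — the appropriate tool for a small a-priori panel
  with few replicates; the unmoderated path is ordinary least squares and
  is tested to match `lm()` exactly. P-values are reported unadjusted by
  design: the intended use is a small pre-declared panel, each gene tested
  at the nominal level.
* **Jonckheere-Terpstra trend test** across at least three ordered groups
  (order taken from the design's explicit level order, never inferred from
  the data). The statistic is the sum of between-pair Mann-Whitney counts.
  The exact null (no ties, total n <= 12) is computed by the classical
  decomposition of the statistic into a convolution of independent
  Mann-Whitney distributions; larger or tied samples use the normal
  approximation with the standard tie-corrected variance.
* **Spearman correlation**: exact permutation p for n <= 9 without ties, t
  approximation otherwise.

All exact modes are validated against full-enumeration oracles in the test
suite (200 random instances per test family).

## SAM-ranked GSEA

The enrichment chain ranks genes by the SAM moderated difference
`d = (mean_1 - mean_2) / (s + s0)`, with `s` the pooled standard error of
the mean difference. `s0 = "auto"` resolves to the median of the per-gene
standard errors — a common simplification; the original
coefficient-of-variation minimization over percentile windows is out of
scope and the resolved value is always recorded. Ranking is descending,
ties broken lexicographically by gene id for determinism.

The enrichment score is the classic Kolmogorov-Smirnov running-sum form:
`+1/k` at set members, `-1/(N-k)` elsewhere, ES the signed value of the
maximal-magnitude excursion (ties between the positive and negative
excursion resolve positive). The default is unweighted
(`weight_exponent = 0`) — the maximal-excursion form with no score
weighting; exponent 1 is available for the score-weighted variant, where
hits contribute `|d|` normalized over the set.

Significance uses **gene-label permutation** (default 2000 permutations):
the ranking is held fixed and the gene labels are shuffled, so set
membership lands on random positions. This is deliberate: with 4 samples
per arm, phenotype permutation would have far too few distinct
rearrangements. Per pathway:

* **nominal p** — sign-matched one tail over all permutations;
* **NES** — ES divided by the mean `|null ES|` of matching sign for that
  pathway;
* **FDR q** — GSEA-style pooling of normalized scores across the pathway
  family (null tail fraction over observed tail fraction, capped at 1);
* **family-wise p** — a maxT procedure: per permutation the family maximum
  of `|NES|` is recorded, and a pathway's FWER p is the fraction of
  permutations whose family maximum reaches its observed `|NES|`. Because
  the nominal p counts a subset of the same permutation events, FWER p >=
  nominal p holds by construction and is asserted in the tests.

The **core enrichment (leading edge) subset** of a negatively enriched
pathway is its members at or after the running-sum minimum (toward the
bottom of the list); mirrored for positive enrichment. Reports always give
both the pathway's nominal size and its expressed size after filtering,
since the two commonly differ.

## The synthetic-data generator

The generator emulates the structure the analyses assume, not any real
dataset: negative-binomial counts with `variance = mu + mu^2 * dispersion`,
log-normal library sizes, log-normal gene-abundance spread (sdlog 1.5,
roughly two decades of dynamic range), gene lengths uniform on 500-5000 nt,
and a planted signature whose mean is multiplied by `2^log2fc` in one
designated group. Defaults are the cohort structure described above: four
groups (CB/NPB/CP/BC) of sizes 3/3/8/9, a 41-gene signature elevated one
log2 unit in the BC-like group, dispersion 0.15, mean library size 2e6
with CV 0.3 — standard bulk-RNA-seq working assumptions where no empirical
values exist to copy. Every generator is a pure function of its
configuration and seed, and the returned truth object (signature members,
per-group true fold changes, sample labels) is sufficient to score every
downstream stage.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: gene-gene correlation (co-regulation
modules), isoform structure, GC/length bias, batch effects, outlier
samples, and signatures whose members move in mixed directions. The
calibration results (type-I error, FDR control) hold under independence
across genes; correlated real data can be less well behaved.

Ancillary generators mirror the two smaller designs: a Gaussian-copula
paired-measurement assay (`simulate_dormancy_assay`; latent correlation
`2*sin(pi*rho/6)` so the *Spearman* correlation hits its target, percent-G0
mapped through the normal CDF onto 0-100) and a 2x2 factorial Gaussian
design (`simulate_factorial_treatment`).

## Problem sizes used in the validation suite

The test suite runs everything at desk scale, chosen to keep the full run
in a few minutes while leaving Monte-Carlo error well inside the asserted
bands: 2000-gene universes with 500 null draws for the calibration
(200 null cohorts) and recovery (100 planted cohorts) studies of the
signature test; 100 null datasets at 500 gene-label permutations for
family-wise error control; 20 seeds for the planted-pathway and
NMF-rank-recovery studies; 200 random instances per exact-test oracle
family. The acceptance script (`scripts/acceptance.R`) runs single
workflows at larger scale (5000-6000 genes, the full 5000 draws / 2000
permutations) and reports what they compute.

## Known limitations

* The FDR q-value follows the GSEA pooling idea but not the desktop
  implementation's exact bookkeeping; the family-wise maxT p is the
  primary corrected quantity here, as it is in the reports this package
  produces.
* `s0 = "auto"` is a percentile rule, not the full SAM tuning procedure.
* The signature test's null draws resample *sets of genes*, so it answers
  "better than a random equally-sized set from this universe", not "better
  than chance labels"; with a small universe heavily contaminated by
  signal genes the null inflates accordingly (the universe should be the
  broad annotation, not a handful of sets).
* Consensus NMF inherits the usual local-optimum caveat of multiplicative
  updates; enough restarts, not tighter tolerances, are the remedy.
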