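---
title: "Integrative miRNA-mRNA analysis with network propagation"
author: "mirmint authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative miRNA-mRNA analysis with network propagation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirmint)
```

## The analysis problem

MicroRNAs repress their target mRNAs post-transcriptionally, so a tumour in
which a miRNA is aberrantly up-regulated tends to show down-regulation of
that miRNA's validated targets, and vice versa. `mirmint` implements a
three-stage integration of a miRNA-seq and an mRNA-seq count matrix from a
two-group design (tumour vs normal germinal-centre B cells in the motivating
application, with very unbalanced arms: 17 vs 4 samples for the small-RNA
assay and 28 vs 5 for mRNA):

1. **Differential expression** of both assays with a negative-binomial
   likelihood-ratio test, calling features at |log2FC| > 2, raw p < 0.01
   and BH-adjusted p < 0.01.
2. **Network-propagation screening** of miRNAs: diffuse influence from each
   miRNA's validated target set through a TF-gene regulatory network by
   random walk with restart, score the influence profile against the ranked
   DE gene list, and normalize by size-matched random gene sets to obtain a
   network perturbation effect score (NPES) with an empirical p-value.
3. **Inverse-correlation pair discovery**: among DE miRNAs and DE genes
   linked by a validated-target edge and changing in opposite directions,
   test each pair's negative expression correlation — and the total number
   of such pairs — against a sample-shuffling permutation null.

A fourth component, the coupled count simulator, generates data with planted
regulatory structure and machine-readable ground truth, and is what the test
suite and the acceptance script calibrate against.

## Differential expression

### Model and test

Counts are modelled as `y[f, s] ~ NB(mu[f] * N[f, s], phi[f])`, where
`N[f, s]` is the sample's effective library size (raw depth times its TMM
factor, times an optional latent-factor correction). For each feature the
per-unit-depth mean is fitted by profile maximum likelihood — a fixed-point
iteration on the score equation, vectorized across features — once pooled
and once per group; twice the log-likelihood difference is referred to a
chi-squared distribution with one degree of freedom. At `phi = 0` the
fitter and likelihood reduce exactly to the Poisson case.

The reported fold change is `log2((mean tumour CPM + c) / (mean normal CPM
+ c))` with prior count `c = 0.5` (units: CPM). The prior guards against
division by zero and is deliberately *not* part of the likelihood, so it
biases no test statistic. Swapping the group labels negates every `log2fc`
and leaves every p-value unchanged, which the suite asserts.

### Dispersion

`phi[f]` (variance = `mu + phi mu^2`) is estimated by the method of moments
on within-group residuals of depth-rescaled counts, floored at zero, then
shrunk toward the median raw dispersion with weight
`prior_df / (prior_df + group_df)`, `prior_df = 10`. With the very small
group sizes this package targets (4-5 normals), per-feature estimates are
noisy and the shrinkage dominates; simulations in the test suite show the
median estimate recovers a true `phi = 0.2` within [0.1, 0.3] and stays
below 0.05 for Poisson data, and that the resulting test's type-I error at
p < 0.01 stays within [0.005, 0.02] on 2,000 null features.

### Filtering and normalization

miRNA matrices are pre-filtered to features with at least 10 CPM in at
least half of the samples (`cpm_min = 10`, `cpm_frac = 0.5`); mRNA matrices
are not filtered by default — the filter exists because a miRNA expressed
below that level is unlikely to regulate anything and contributes almost no
statistical information. Normalization factors are trimmed-mean-of-M-values
(30% M-trim, 5% A-trim, reference = sample whose upper quartile is closest
to the mean upper quartile, factors rescaled to geometric mean 1), computed
by edgeR's implementation behind the `norm_factors()` surface. The factors
matter: planted fold changes shift library composition, and the suite
checks the factors against the oracle correction implied by the known
simulation means.

### Latent factors

Real cohorts assembled from multiple studies carry batch structure. In place
of a full surrogate-variable analysis, `estimate_latent_factors()` takes the
SVD of group-mean-centred `log2(CPM + 1)` (column-centred as well, because
per-sample depth offsets are already absorbed by the model's library-size
offsets and would otherwise always surface as a spurious leading factor)
and selects the number of factors by parallel analysis: each residual row is
permuted independently 20 times, and a leading component is kept while its
*variance proportion* exceeds the 95th percentile of its permuted
counterpart. Variance proportions, not raw singular values, are compared
because re-centring the permuted matrix slightly deflates its total
variance. Selected factors enter the NB test through per-feature,
per-sample offset corrections (an OLS fit of the centred log-expression on
the factors). With `k = 0` the test is bit-identical to the unadjusted one.

## Network propagation (NPES)

### Walk

The regulatory network has typed edges: miRNA -> gene (validated target)
and TF -> gene. Propagation runs on the gene-level subgraph (TF edges
only). The walk operator is
`p <- (1 - r) (W p + m p0) + r p0`, with `W` the column-normalized
adjacency, `p0` uniform over the seed set (the miRNA's targets), restart
`r = 0.5`, and `m` the mass on dangling genes, which is returned to the
restart vector so that influence always sums to one. `rwr()` iterates to an
L1 tolerance of 1e-10 (cap 1,000 iterations). Because the fixed point is
`K p0 / sum(K p0)` with `K = (I - (1 - r) W)^{-1}`, the screen computes `K`
once and evaluates each permutation by column sums — identical results
(asserted to 1e-9 in the tests) at a small fraction of the cost.

### Score

The influence vector is scored against the ranked DE list with a weighted
running sum: walking the ranking top to bottom, hits (influence above
`eps = 1 / (10 N)`, which excludes numerically negligible influence) add
their share of the total hit influence, non-hits subtract `1 / (N - |H|)`;
the raw score is the signed maximal deviation, and the leading edge is the
hit set at or before a positive extremum (after a negative one).

The default ranking statistic is the **unsigned** significance
`-log10(p_raw)`. This is a deliberate design choice: an up-regulated driver
represses its targets, so under a signed ranking those targets sit at the
bottom, the extremum is negative, and a one-sided "score at least as large
under random gene sets" p-value can never be small for exactly the miRNAs
the screen exists to find. Ranking by magnitude of dysregulation makes a
true driver's target set cluster at the top regardless of direction, and
positive NPES then reads as "this miRNA's influence concentrates on
strongly dysregulated genes". `ranked_de_list(signed = TRUE)` restores the
signed variant for users who want directional enrichment. Ties are broken
by feature ID so rankings are strict and deterministic.

### Permutation normalization

To avoid favouring miRNAs with large target sets, each miRNA's raw score is
normalized by `B` random seed sets of identical size drawn uniformly
without replacement from the network's genes: `npes = (S - mean(S_b)) /
sd(S_b)`, `p_emp = (1 + #[S_b >= S]) / (1 + B)` (the +1 correction makes
p = 0 impossible). `B = 1000` by default. A degenerate null (`sd = 0`) flags
the record and excludes it from the BH adjustment. A miRNA is *enriched*
when `npes > 2` and its BH-adjusted p passes both the 0.05 and 0.1
thresholds (two printed cut-offs applied to the same adjusted value; the
distinction between them is not explained in the motivating analysis, so
both are exposed). Each miRNA's permutation stream is seeded from the
global seed plus a hash of its identifier, making results independent of
screen order. An optional family map collapses member target sets so that
families are scored as units. Note that at `B = 200` the smallest
achievable BH-adjusted p across ~50 miRNAs (~0.055) already exceeds the
0.05 threshold, so enrichment calls require `B` near the default 1,000;
scaled-down `B` is appropriate only for rank-based calibration studies.

## Pair discovery

Candidates are (miRNA, gene) pairs with both members DE, a validated-target
edge, and opposite directions. Correlations are Pearson, computed on
`log2(CPM + 1)` (per-assay TMM factors) over the sorted intersection of the
two assays' sample IDs — all shared samples by default; a `samples`
argument restricts to a subset (e.g. tumours only), since whether the
correlation should span both groups is genuinely ambiguous. Pairs constant
across shared samples are dropped with a message.

The permutation test shuffles the miRNA matrix's sample alignment relative
to the mRNA matrix — one joint shuffle per permutation shared across pairs,
which preserves each assay's internal structure (and the dependence between
pairs) while breaking exactly the cross-assay coupling under test. Per-pair
significance is left-tailed (`p_perm = (1 + #[r_b <= r_obs]) / (1 + B)`,
significant iff `p_perm < 0.05` and `r_obs < 0`); the global test compares
the observed count of significant pairs with each permutation's count of
pairs that are extreme within their own null distribution, so the null of
the count statistic inherits inter-pair dependence. `B = 10000` by default.

One caveat the simulator makes visible: when both assays carry strong
group-level DE, sample shuffles that map tumours to tumours retain part of
the group-driven anti-correlation, so the per-pair permutation p measures
coupling *beyond* what group membership alone explains. Null calibration in
the tests is therefore run on effect-free simulations, where exchangeability
is exact and the significant fraction sits at the nominal 0.05.

## The simulator

`simulate_network()` gives every miRNA `targets_per_mirna` uniform targets
and every TF (a gene) `genes_per_tf` out-edges. `simulate_counts()` draws
per-feature baselines log-normally (`meanlog = log(50)`, `sdlog = 1.5`,
natural-log scale — a typical right-skewed expression profile), plants:

* `n_drivers = 5` up-regulated driver miRNAs at `lfc_mirna = 3` log2 units,
* `n_down_mirnas = 5` down-regulated miRNAs at the same magnitude,
* independent DE genes (`frac_de_genes = 0.1` of genes at |log2FC| = 3),
* repression of each driver's targets by `repression_lfc = -1.5` per
  driver, summed over a gene's drivers and capped at -4,

and couples drivers to targets through a per-sample activity variable
`a[d, s] = is_tumor(s) + z`, `z ~ N(0, activity_sd = 0.3)`: the driver's
log2 shift is `lfc_mirna * a` and each target's is its capped total
repression times the mean activity of its drivers. Tying the coupling to
the planted fold changes (rather than adding an independent noise term)
means planted pairs anti-correlate within groups as well as across them,
which is the signal the pairing stage tests. Counts are negative binomial
(`dispersion = 0.2`; 0 gives Poisson) at log-normal library depths around
1e6 (miRNA) and 2e7 (mRNA), mimicking assay depth asymmetry. Group sizes
default to the small-RNA arm (17 vs 4); `preset = "mrna_arm"` switches to
28 vs 5. An optional batch multiplies a random 30% of features by
`2^batch_shift` in alternating samples. Everything is reproducible from the
config seed, and `write_truth()` serializes the planted structure.

What the simulator does *not* emulate: sequence-level effects (seed-match
strength, target-site counts), miRNA families with shared seeds, partially
overlapping sample sets between assays beyond simple ID intersection,
compositional extremes, and real batch structure more complex than one
binary factor. Passing tests therefore demonstrate internal statistical
correctness and calibration, not fidelity to any particular real cohort.

## Numerical and design notes

* **Problem sizes.** The packaged analyses run at desk scale: 300 genes,
  30-55 miRNAs, 17 + 4 samples, `B` of 200-1,000 for calibration loops and
  1,000/10,000 for single end-to-end runs — large enough for stable
  estimates, small enough that the full suite runs in about a minute.
* **BH adjustment** is the standard step-up (via `stats::p.adjust`),
  validated in the suite against a literal implementation of the
  definition. It is *not* idempotent (re-adjusting adjusted values inflates
  them); the suite asserts the true properties: oracle equality,
  elementwise domination of the input, and order preservation.
* **Worked-example table.** The packaged 49-miRNA DE table stores its two
  printed p-value columns verbatim (`p_raw` := the "BH adjusted p-value"
  column, `p_adj` := the "FDR" column); reclassifying from the numeric
  columns reproduces every printed regulation label, and 22 up / 27 down /
  7 down-regulated let-7 members are recomputed, not stored.
* **Determinism.** Every stochastic stage takes a seed; the pipeline
  derives per-stage seeds from its global seed by fixed offsets, and two
  runs with the same configuration produce byte-identical output files.
* **Degenerate inputs.** Zero library sizes, duplicate identifiers, unknown
  edge types, miRNA/gene identifier collisions, empty hit sets and
  non-convergent walks all raise informative errors; empty candidate sets
  and empty networks propagate as empty results with warnings.

## A minimal run

```{r example, eval = FALSE}
cfg <- pipeline_config(outdir = "mirmint-demo", seed = 1,
                       sim = sim_config(seed = 1))
res <- run_pipeline(cfg)
res$report
```

The report lists DE counts for both assays, the number of NPES-enriched
miRNAs, candidate and significant inverse pairs, and the global permutation
p-value; all stage tables are written as TSV under the output directory.
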