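# mirmint

Integrative analysis of miRNA and mRNA sequencing counts from two-group
(tumour vs normal) designs, built around the regulatory logic of
miRNA-mediated repression: an up-regulated miRNA should push its validated
target genes down, and the network consequences of that push should explain
part of the observed differential-expression profile.

The package is aimed at transcriptomics analysts who have a miRNA count
matrix, an mRNA count matrix, a sample sheet, and prior-knowledge edge
lists (validated miRNA→target interactions and a TF→gene regulatory
network), and who want a reproducible, testable pipeline from counts to
candidate regulator miRNAs and miRNA–mRNA pairs.

## What it computes

**1. Differential expression.** A negative-binomial likelihood-ratio test
per feature: `y[f,s] ~ NB(mu[f]·N[f,s], phi[f])`, with profile-ML group
means at moment-estimated, shrinkage-stabilized dispersions, TMM effective
library sizes, optional residual-SVD latent factors as covariates, and
Benjamini–Hochberg control. Features are called at |log2FC| > 2, raw
p < 0.01 and adjusted p < 0.01; miRNAs are pre-filtered to ≥ 10 CPM in at
least half the samples.

**2. Network perturbation effect scores (NPES).** For each miRNA, influence
diffuses from its target set through the TF–gene network by random walk
with restart (`p ← (1−r)(Wp + m·p0) + r·p0`, r = 0.5); the influence
profile is scored against the ranked DE gene list with a weighted
running-sum statistic (signed maximal deviation; leading-edge genes at the
extremum), and normalized by B size-matched random gene sets:
`NPES = (S − mean S_b)/sd S_b`, with an empirical p-value and BH control
across miRNAs. Enriched miRNAs have NPES > 2 and adjusted p below 0.05 and
0.1.

**3. Inverse-correlation pairs.** Candidates are (DE miRNA, DE target gene)
pairs with opposite directions; each gets a Pearson correlation on
log2(CPM+1) over the assays' shared samples, a left-tailed permutation
p-value from B joint sample-shuffles of one assay against the other, and
the observed count of significant pairs gets a global permutation p.

**4. Synthetic benchmarks.** A coupled NB count simulator with planted
driver miRNAs, repressed targets, independent DE genes, optional batch
effects, and ground-truth output, used throughout the tests to calibrate
type-I error, sensitivity, driver recovery and permutation-null behaviour.

The methods vignette (`vignettes/mirna-mrna-integration.Rmd`) documents the
models, defaults and design choices in detail.

## Worked example

The package ships a published worked-example table of 49 miRNAs
differentially expressed between endemic Burkitt lymphoma tumour cells and
germinal-centre B cells. Reclassifying it from its numeric columns
reproduces the printed labels:

```r
library(mirmint)
str(table1_report())
#> List of 4
#>  $ n_total    : int 49
#>  $ n_up       : int 22
#>  $ n_down     : int 27
#>  $ n_let7_down: int 7
```

49 differentially expressed miRNAs, 22 up- and 27 down-regulated in the
tumour cells, including 7 down-regulated let-7 family members.

An end-to-end run on simulated data (30 miRNAs incl. 5 planted drivers and
5 planted down-regulated miRNAs, 300 genes, 17 tumours vs 4 normals):

```r
cfg <- pipeline_config(outdir = "mirmint-demo", seed = 1,
                       sim = sim_config(seed = 1),
                       netprop = list(B = 1000), pairing = list(B = 10000))
res <- run_pipeline(cfg)
#> [simulate] seed=1 30 miRNAs x 300 genes x 21 samples
#> [de] seed=1 miRNA up=4 down=4 | mRNA up=16 down=21
#> [netprop] seed=1 30 miRNAs screened, 4 enriched
#> [pairs] seed=1 9 candidates, 7 significant, global p=0.0006999
```

The text report summarizes the run:

```
Integrative miRNA-mRNA analysis report
  DE genes:  37 (16 up, 21 down)
  DE miRNAs: 8 (4 up, 4 down)
  Enriched miRNAs (propagation screen): 4
  Inverse-change pairs: 9 candidates, 7 significant
  Global pair-count permutation p: 0.0006999
```

Reading it: 37 genes and 8 miRNAs pass the stringent DE thresholds (the
planted ±3 log2FC miRNAs; per-target repression of −1.5 sits below the
|log2FC| > 2 call threshold by design, so repressed targets mostly surface
through the propagation and pairing stages instead); 4 miRNAs are
NPES-enriched regulator candidates; and 7 of 9 candidate inverse pairs are
individually significant, with the pair count far exceeding the shuffle
null (global p ≈ 7e-4). Per-stage TSVs (`de_*.tsv`, `npes.tsv`,
`pairs.tsv`, `report.tsv`) land in the output directory, and a rerun with
the same configuration is byte-identical.

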