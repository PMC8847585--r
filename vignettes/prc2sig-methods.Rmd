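---
title: "Methods: multi-omic discovery of PRC2 direct-target signatures"
author: "prc2sig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omic discovery of PRC2 direct-target signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prc2sig)
```

## Scope and model

`prc2sig` implements a multi-omic procedure for finding the genes that a
PRC2 inhibitor directly de-represses. The underlying biological model is
bivalency: PRC2 targets carry high promoter H3K27me3 together with
moderate H3K4me3, and removing H3K27me3 releases their transcription.
The procedure therefore (i) quantifies promoter chromatin state per
gene, (ii) types genes by unsupervised clustering of features that do
*not* include H3K27me3, (iii) identifies the PRC2-target type post hoc
as the cluster with maximal held-out H3K27me3, and (iv) intersects that
type with the up-regulated DEGs to form the signature. Holding H3K27me3
out of clustering keeps the labeling step an independent check rather
than a self-fulfilling input.

## Spike-in normalization

Per-library standardization factors are
`SF_i = min(UMD)/UMD_i`, where `UMD_i` counts de-duplicated reads
uniquely matched to the exogenous spike-in genome; target-genome counts
are multiplied by `SF_i`. The implied spike-in depth `UMD_i * SF_i` is
constant across libraries after scaling (a test asserts this exactly),
while genuine genome-wide differences in the target signal — the whole
point of spiking in — are preserved. Factors are undefined for empty
spike-in libraries; zero counts are an error rather than a silent guard.

## Promoter quantification

Per-gene signal is the length-weighted mean of bedGraph values over a
strand-aware window around the TSS, with uncovered bases counting as
zero and the denominator fixed at the clipped window length, so values
stay depth-comparable after spike-in scaling. The window defaults to
TSS ± 3000 bp, matching the composite-profile range (−3 kb to +3 kb);
the per-gene window choice is configurable because published per-gene
quantifications do not always state it. Conventions: coordinates are
BED-compatible (0-based half-open externally, 1-based closed inside R);
the TSS of a minus-strand gene is its rightmost base; minus-strand
metagene bins are reversed so profiles read 5′→3′. A brute-force
per-base oracle validates the weighted means on small tracks.
Methylation is the pooled beta `sum(meth)/sum(total)` over promoter
CpGs; genes without CpG coverage are reported as missing rather than
imputed.

## Differential expression

The two-condition test is a deliberately small, self-contained
negative-binomial Wald test rather than a wrapper around a large DE
framework: median-of-ratios size factors; fold change
`log2((mT + pc)/(mC + pc))` on normalized means with a default
pseudocount of 1 to stabilize zeros; gene-wise dispersions estimated by
method of moments and pooled within ~20 equal-occupancy bins of similar
mean (the pooled estimate uses a bias-corrected `mu^2`, which keeps the
null type-I error at nominal level with triplicates); a delta-method
standard error and a two-sided normal p-value. No empirical-Bayes
shrinkage and no independent filtering are applied. A test cross-checks
fold-change and p-value concordance against an independent NB fit
(DESeq2) on a small simulation, and a seeded null simulation keeps the
type-I error within [0.03, 0.07] at α = 0.05. DEG calls use the
inclusive thresholds log2FC ≥ 1 (≤ −1) and BH-adjusted p ≤ 0.05.

## Typing and model selection

Features {expression log2FC, methylation beta, H3K4me3, ATAC} are
z-scored with the population (divisor *n*) standard deviation;
zero-variance columns map to zeros instead of erroring. Clustering is
k-means with k-means++ seeding and Lloyd iterations (tolerance 1e-6 on
the inertia decrease, 300-iteration cap, 10 restarts, best inertia
wins); empty clusters are reseeded to the farthest point. The number of
types is chosen as the argmax of the mean silhouette over k = 2..10 —
the "elbow" of a silhouette curve is ill-defined when the curve is not
monotone, so the maximum is used and the full per-k table is always
returned so users can override the automatic choice. Ties in the
silhouette, and in the H3K27me3 means used for labeling, break toward
the smaller k / lower cluster index for determinism. Genes missing any
feature are dropped before clustering and enumerated.

Semantic labels are descriptive only (the PRC2-target label is the one
that matters downstream): the H3K27me3-high cluster is `prc2_target`;
other clusters take their name from their dominant centroid feature,
with all-negative centroids called `quiescent` and near-origin
centroids `baseline`.

## Enrichment statistics

Fisher-exact enrichment is the upper-tail hypergeometric probability at
fixed margins, with the sample odds ratio `ad/bc`; a brute-force
enumeration over all fixed-margin tables serves as the oracle in tests.
The preranked GSEA is a minimal reimplementation: hits increment the
running sum by `|score|^weight` (normalized), misses decrement by
`1/(N − |S|)`, ES is the signed maximal deviation, and the null
permutes gene labels with `p = (1 + #{|ES*| ≥ |ES|})/(nPerm + 1)` — the
+1 correction avoids zero p-values; NES divides by the same-sign
permutation mean. Desktop GSEA implementations differ in their null
(phenotype vs gene permutation) and NES conventions; this package
documents its variant rather than claiming equivalence. Kruskal–Wallis
uses midrank ties correction; the all-tied degenerate case is defined
as H = 0, p = 1.

## Cohort validation

Samples are stratified by a marker (regulator) gene's expression with a
tie-inclusive percentile rule: low group ≤ the 25th-percentile value,
high group ≥ the 75th-percentile value. Real cohorts produce groups
slightly off n/4 under ties (e.g. 126/125 of 498), which is why the rule
is tie-inclusive and group sizes are always reported. Fold change is
computed on the linear scale recovered from log2(RPM), as
`log2((meanLow + pc)/(meanHigh + pc))` with a default pseudocount of
1 RPM — a mean-ratio form chosen because published stratified-FC
formulas often live in supplements; both the form's pseudocount and the
optional per-gene rank-sum filter are configurable.

## The synthetic generator

`simulateStudy()` emulates the statistical structure of such a study
with five gene archetypes — baseline, methylated (high CpG
methylation), quiescent (low everything), active (high H3K4me3/ATAC)
and prc2_target (high H3K27me3, moderate H3K4me3, closed chromatin,
up-regulated by treatment). Defaults, chosen once as a realistic
desk-scale benchmark: 2000 genes in fractions 0.35/0.15/0.15/0.20/0.15;
promoter mark levels per archetype as tabulated in the package source,
painted as 50-bp bedGraph bins over TSS ± 3 kb with lognormal gene- and
bin-level noise (sdlog 0.3 and 0.15); the pairwise archetype separations
in z-space are deliberately comparable in magnitude (≈2–3 within-cluster
radii), so no single merge dominates the silhouette curve. Counts are
negative-binomial (dispersion 0.05, mean 200, lognormal gene baselines,
triplicates per arm — the usual RNA-seq design) with a +2 log2FC
treatment effect on prc2_target genes; spike-in depths are Poisson
around configured values. The validation cohort (498 samples, the size
of the public neuroblastoma set used for this kind of validation) draws
a latent factor shared between an EZH2-like marker (negatively, target
correlation −0.8) and prc2_target genes (positively, loading 1.5 in
log2 units).

Every generator draws from a named sub-stream of the master seed
(`.subSeed`), so any component is reproducible regardless of call
order. With `signalNoise = 0`, promoter bins equal archetype means
exactly — the noise-free limit used in tests.

What the generator does *not* emulate: read-level sampling (FASTQ),
realistic sequence composition, peak shapes beyond flat promoter
windows, copy-number or batch structure, and correlated dispersion
trends. Passing tests on this benchmark therefore demonstrates that the
pipeline's statistics and bookkeeping are correct and that the design is
recoverable under its stated noise model — not that any particular real
dataset would yield a specific signature.

## Problem sizes and numerical choices

The reference benchmark (2000 genes, k = 2..10, 10 restarts, silhouette
on a 2000-point distance matrix) runs in well under a minute; the test
suite uses 250–500-gene versions of the same design for unit-level
checks and the full benchmark in the end-to-end suite. Tolerances:
k-means stops on an inertia decrease ≤ 1e-6; z-scoring treats sd = 0
columns as all-zero; BH and Fisher computations are exact; permutation
p-values are bounded below by `1/(nPerm + 1)` by construction.

## Known limitations

The NB test's normal Wald approximation is anti-conservative for very
low counts (the pseudocount masks, but does not fix, mean estimates
near zero); silhouette-based selection can under-split nested clusters
whose separations differ by an order of magnitude; the GSEA NES is not
comparable across tools; and the cohort fold-change form is one of
several reasonable conventions — all parameters involved are exposed
rather than hard-coded.
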