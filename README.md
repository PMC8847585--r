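# prc2sig

Discovery of PRC2 direct-target gene signatures from multi-omic data.

## The problem

Polycomb Repressive Complex 2 (PRC2) silences developmental genes by
depositing H3K27me3 at their promoters. When PRC2 is inhibited
pharmacologically, only a subset of H3K27me3-marked genes is actually
de-repressed — typically bivalent genes that also carry H3K4me3 and are
poised for activation. Identifying that subset (the *direct-target
signature*) from chromatin and expression profiling is the task this
package automates, for computational biologists analyzing
PRC2-inhibitor studies:

1. **Spike-in normalization** of ChIP-seq libraries. With an exogenous
   (e.g. Drosophila) chromatin spike-in, each library *i* gets a
   standardization factor from its spike-in matched read count UMD:

   SF_i = min(UMD_1, …, UMD_n) / UMD_i,  NH_i = SF_i × OH_i

   so genuine genome-wide H3K27me3 loss stays visible after scaling.
2. **Promoter quantification**: strand-aware, length-weighted mean
   signal in TSS ± 3 kb windows from bedGraph tracks; composite
   (metagene) TSS profiles; pooled CpG methylation betas.
3. **Differential expression**: a self-contained negative-binomial Wald
   test (median-of-ratios normalization, binned method-of-moments
   dispersion, delta-method standard error) with Benjamini–Hochberg
   correction and DEG calls at |log2FC| ≥ 1, FDR ≤ 0.05.
4. **Epigenetic typing**: k-means (k-means++ seeding, Lloyd iterations,
   restarts) on the z-scored features {expression log2FC, methylation,
   H3K4me3, ATAC}, with k chosen by mean silhouette over k = 2..10.
   Promoter H3K27me3 is deliberately **held out** of clustering and used
   only afterwards to label the H3K27me3-high cluster as the PRC2-target
   type. The signature is that type intersected with the up-DEGs.
5. **Enrichment statistics**: one-sided Fisher-exact tests on gene sets
   (GMT) with BH correction, and a minimal preranked GSEA (running-sum
   enrichment score, gene-permutation null).
6. **Cohort validation**: stratify an independent expression cohort into
   low/high quartile groups of a regulator gene (e.g. EZH2), compute
   per-gene log2 fold changes between groups, and compare the epigenetic
   types with the Kruskal–Wallis test — PRC2 targets should be highest
   where the regulator is low.

A synthetic multi-omics generator (`simulateStudy()`) emulates the whole
study design — five gene archetypes with distinct promoter profiles,
negative-binomial counts with treatment-induced up-regulation of the
bivalent archetype, spike-in depths, and an anti-correlated validation
cohort — with known ground truth, so every stage is testable without any
sequencing data.

## Worked example

```r
library(prc2sig)

sim <- simulateStudy(synthConfig(nGenes = 500, cohortN = 120, seed = 42))
sf  <- studyFeatures(sim)                      # quantify + DE test
model <- selectK(zscoreFeatures(sf$features), kRange = 2:8, seed = 42)
model <- assignTypes(model, sf$features@heldout)
model
#> EpitypeModel: k = 5 over 500 genes; inertia = 279.565
#> cluster sizes:
#>      1 (active)    2 (baseline)   3 (quiescent)  4 (methylated) 5 (prc2_target)
#>              99             176              75              75              75
#> model selection: mean silhouette maximized at k = 5
```

Model selection recovers the five simulated archetypes, and the held-out
H3K27me3 labels cluster 5 as the PRC2-target type. Overlapping it with
the up-regulated DEGs gives the signature:

```r
overlapSignature(typeGenes(model, "prc2_target"), sf$degCalls$up)
#> SignatureResult: |type| = 75 |up-DEGs| = 75 |signature| = 75
```

Cohort validation: split the simulated 120-sample cohort by EZH2
quartiles and compare stratified fold changes across types —

```r
cl <- clusterAssignments(model)
types <- setNames(unname(typeMap(model)[as.character(cl)]), names(cl))
fc <- stratifiedFC(sim@cohort, quartileSplit(sim@cohort))
out <- typeFCSummary(fc[names(types)], types)
print(out$summary, digits = 3)
#>          type   n     q25   median    q75
#> 1      active  99 -0.0691 -0.00455 0.0672
#> 2    baseline 176 -0.0945 -0.01278 0.1012
#> 3  methylated  75 -0.0677 -0.00260 0.0730
#> 4 prc2_target  75  2.0750  2.18423 2.3353
#> 5   quiescent  75 -0.0726 -0.00198 0.0890
```

Only the PRC2-target type is up where EZH2 is low (median log2FC 2.18 vs
~0 for every other type; Kruskal–Wallis H = 191.1, p = 3.1e-40) — the
expected fingerprint of direct PRC2 targets.

`runPipeline()` executes all stages under one configuration and writes
every artifact with a checksummed manifest and a JSON run report;
`inst/scripts/prc2sig.R` wraps it for the shell.

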