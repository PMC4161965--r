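# gsaperm

Gene set association analysis of RNA-seq count data between two phenotype
groups, with significance assessed by **sample permutation**.

Given a raw gene-by-sample count matrix, two-class phenotype labels, and a
collection of gene sets (pathways), `gsaperm` answers: *which pathways are
differentially active between the two groups?* It is aimed at
transcriptomics analysts comparing conditions, tissues, or disease subtypes
with pathway collections such as MSigDB canonical pathways.

## Method

The pipeline has four stages:

1. **Normalization.** A pseudocount of 1 is added to all counts and each
   sample is scaled by its median-of-ratios size factor
   (s<sub>j</sub> = median<sub>g</sub> x<sub>gj</sub> / (∏<sub>j'</sub>
   x<sub>gj'</sub>)<sup>1/n</sup>, the DESeq normalization).
2. **Gene-level differential expression.** For each gene a signed score
   between the two classes: `signal2noise` (m₁ − m₂)/(s₁ + s₂),
   `log2ratio` log₂(m₁/m₂), or `signal2noise_log2ratio`, the
   sign-preserving geometric mean of the two. Per-gene empirical p-values
   come from the permutation ensemble.
3. **Set-level association score (AS).** Any of ten statistics aggregates
   the member genes of each set: score-based (`weighted_ks` — the weighted
   Kolmogorov–Smirnov enrichment score, `l2norm`, `mean`,
   `weighted_sig_ratio`, `sig_ratio`), p-value-combination
   (`geometric_mean`, `truncated_product`, `fisher`, `min_p`), or
   rank-based (`rank_sum`).
4. **Significance.** Phenotype labels are shuffled N times (default 2000)
   and all statistics recomputed per shuffle, preserving gene–gene
   correlation in the null. Each set's AS is normalized by its null mean
   (NAS = AS / mean<sub>π</sub> AS<sub>π</sub>), and empirical p-values,
   FDR, and FWER are computed from the null NAS distribution, one-sided in
   the direction in which each statistic signals association. A
   gene-permutation mode (shuffling gene identities instead of labels) is
   also available for comparison.

A negative-binomial simulation module generates datasets with a known
16-gene causal set under six scenarios of signal strength, and an
evaluation module computes recognition rates, power, and the top-K
occurrence / average-rank aggregation used to combine results across
methods.

## Worked example

Simulate a small two-group experiment whose first gene set contains truly
differentially expressed genes, then analyse it:

```r
library(gsaperm)

sim <- simulate_dataset(scenario_config("S6", seed = 1,
  n_genes = 120, n_samples_per_class = 20, n_sets = 10,
  set_size_range = c(5, 20)))
res <- run_gsa(sim$counts, sim$labels, sim$sets, n_perm = 50,
               min_size = 3, max_size = 50, seed = 1)
res
#> Gene set association analysis (signal2noise:l2norm, sample permutation, N = 50)
#> 10 gene sets over 120 genes
#>
#>       NAME SIZE     AS    NAS PVALUE    FDR FWER
#> 1  SET_001   16 6.8454 11.460   0.00 0.0000 0.00
#> 2  SET_004   17 0.8741  1.362   0.00 0.1040 0.38
#> 3  SET_005   20 0.9837  1.412   0.02 0.1050 0.34
#> ...
```

The causal set (`SET_001`) has an L2-norm association score of 6.85 —
11.5 times its permutation-null mean (NAS) — and none of the 50 label
shuffles produced anything as extreme anywhere in the collection
(p = FDR = FWER = 0), so it ranks first. The remaining (null) sets have
NAS near 1 and unremarkable significance. Tables are sorted by FDR, ties
broken by NAS extremity.

With files on disk the same analysis runs from the shell:

```sh
gsaperm run --counts counts.tsv --cls labels.cls --gmt sets.gmt \
        --set-stat l2norm --permutations 2000 --seed 1 --out result.tsv
```

(`exec/gsaperm` is installed with the package; `simulate`, `evaluate`, and
`aggregate` subcommands drive the simulation and cross-method summaries.)

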