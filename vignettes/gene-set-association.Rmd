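---
title: "Permutation-based gene set association analysis of count data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Permutation-based gene set association analysis of count data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsaperm)
```

## The model

`gsaperm` tests, for each gene set $S$ in a collection, whether the
expression of its member genes differs between two phenotype classes in an
RNA-seq count experiment. The test statistic is built in two layers.

**Gene layer.** After adding a pseudocount of 1 and dividing each sample by
its median-of-ratios size factor, each gene receives a signed
differential-expression score between the classes. Three scores are
available:

* `signal2noise`: $(\mu_1 - \mu_2)/(\sigma_1 + \sigma_2)$, with each class
  standard deviation floored at $\max(\sigma, 0.2\,|\mu|, 10^{-8})$. The
  floor guards genes whose within-class variation is negligible relative to
  their mean (common after normalization of high-count genes), where an
  unfloored ratio would explode.
* `log2ratio`: $\log_2(\mu_1/\mu_2)$, defined everywhere because the
  pseudocount makes all normalized values positive.
* `signal2noise_log2ratio`: $\mathrm{sign}(M)\sqrt{|S|\,|M|}$ for
  signal-to-noise $S$ and log-ratio $M$. We chose the sign-preserving
  geometric mean as the combination rule because it is symmetric in its
  components, antisymmetric under class swap (like both components), zero
  iff either component is zero, and dimensionally balanced between the
  two. It is isolated behind one function so an alternative combination
  can be swapped in without touching anything else.

**Set layer.** An association score $AS(S)$ aggregates the member genes.
Ten statistics are implemented in three input families: gene-score based
(the weighted Kolmogorov–Smirnov running-sum enrichment score with weight
exponent $p$, the L2 norm $\sqrt{\sum s_g^2}$, the mean of $|s_g|$, and two
significance-ratio statistics), gene-p-value based (geometric mean,
truncated product, Fisher's $-2\sum\log p$, minimum p), and rank based
(sum of the members' global significance ranks). Each statistic has a
fixed direction of association: larger is more significant for the five
score statistics and Fisher's method, smaller for the geometric mean,
truncated product, minimum p, and rank sum.

## Significance by sample permutation

The phenotype labels are shuffled $N$ times and every quantity above is
recomputed per shuffle with the identical code path. Because whole samples
are relabelled, the correlation structure among genes — which is strong
within pathways — is preserved in the null, which is the core argument for
sample permutation over gene permutation.

For each set, the normalized association score is the observed AS divided
by its null mean, $NAS = AS_0 / \overline{AS_\pi}$, correcting for
heterogeneity of set size and internal correlation. The empirical p-value
is the plain fraction of permutations at least as extreme as the observed
AS (ties in the tail); FDR compares each set's NAS against the pooled null
NAS of all sets, and FWER against the per-permutation extreme (maximum for
greater-tail statistics, minimum for smaller-tail ones), clipped to
$[0,1]$. No isotonic smoothing is applied to the FDR beyond the clip, so
small non-monotonicities along the NAS ordering can occur; they are a
property of the estimator, not a bug.

The signed KS statistic is handled within same-sign groups, as enrichment
analyses conventionally do: positive scores are normalized by the mean of
the positive null values and compared against them, negative against
negative. An exact magnitude tie between the positive and negative
running-sum extremes yields 0 — such ties are structurally common (hit
weights sum to one and miss penalties are rational), so the tie is detected
within a $10^{-12}$ band to keep the result independent of floating-point
summation order.

### Per-gene p-values

The p-value family needs a per-gene p-value for observed *and* permuted
data. Every column of the score matrix — the observed assignment and each
permutation — is scored against the pooled collection of all $N+1$ columns:
$p_g = \#\{c' : |s_{g,c'}| \ge |s_{g,c}|\}/(N+1)$. Including the column
itself makes the minimum attainable p-value $1/(N+1)$ and, crucially, makes
all columns exchangeable under the null. An asymmetric convention (scoring
the observed column against only the $N$ permutations, where $p=0$ is
possible, while permutation columns always tie with themselves) makes the
observed column stochastically more extreme than its null and inflates the
type-I error of every p-value-based set statistic — we measured null
fractions of $p<0.05$ between 0.08 and 0.30 under that convention before
adopting the pooled one, after which all ten statistics calibrate (see
below).

In gene-permutation mode there are no label shuffles, so per-gene p-values
are cross-gene tail probabilities $\#\{h : |s_h| \ge |s_g|\}/G$ — exactly
the null that gene permutation samples from.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `n_perm` | 2000 | label permutations; 200 is used in the reduced-scale benchmark runs, 5000 is typical for tissue-scale analyses |
| `min_size`, `max_size` | 15, 100 | inclusive bounds on *intersected* set size (set ∩ measured genes); sets outside are dropped before analysis |
| `alpha` | 0.05 | gene-significance threshold of the two ratio statistics |
| `tau` | 0.05 | truncation point of the truncated product |
| `ks_exponent` | 1 | KS hit-weight exponent; 0 recovers the classic unweighted KS |
| `seed` | — | single integer driving the whole permutation stream |

The size bounds are applied to the intersection with the measured genes
because a nominal 300-gene pathway of which 40 are measured behaves like a
40-gene set. Boundary semantics are inclusive: sets of exactly 15 or
exactly 100 intersected genes are retained.

## The simulation framework

`simulate_dataset()` emulates a two-class count experiment with a known
causal pathway: 1000 genes × 400 samples (200 per class), 100 gene sets of
which the first is a 16-gene causal set; the remaining 99 sets draw only
from the 984 non-causal genes (with overlap allowed between sets). Counts
are negative binomial with gene-specific baseline means
($\log_2 \mu_g \sim U(3, 10)$, a typical bulk RNA-seq expression range) and
dispersion 0.15 (variance $\mu + 0.15\mu^2$, mid-range for bulk tissue).
Six scenarios vary the number of differentially expressed causal genes
(8 or 12 of 16) and the absolute log2 fold change of each
($U[0.8,1]$, $U[1,3]$, or $U[2,4]$): S1–S3 use 8 DE genes with increasing
effects, S4–S6 use 12.

Design choices that were genuinely open:

* **Effect direction.** One association direction is drawn per causal set
  and replicate and shared by its DE genes (`effect_sign = "set"`),
  reflecting a common upstream driver of the set's activity — the setting
  in which the published recognition rates of the directional KS statistic
  are attainable. Independent per-gene signs (`effect_sign = "gene"`)
  split the causal genes across both tails of the ranking; sign-invariant
  statistics (L2 norm, mean, all p-value statistics) are unaffected, but
  the signed KS score collapses toward zero and cannot recover the set.
  Both options are exposed.
* **Library size.** Constant by default (size factors ≈ 1) so that
  statistic behavior is isolated from normalization; an optional
  per-sample depth multiplier $U(0.5, 2)$ exercises the normalization
  path.
* **Non-causal set sizes** are uniform on $\{15,\dots,100\}$, surviving
  the default size filter while exercising set-size heterogeneity.

What the generator deliberately does **not** emulate: biological
between-sample variation beyond the NB dispersion, gene–gene correlation
among null genes (null sets are internally independent, so the sample
permutation advantage of preserving correlation is not visible here),
gene-length effects, outlier samples, or unbalanced designs. Passing
recognition-rate benchmarks on these data therefore demonstrates that the
statistics and significance machinery work as specified, not that any
particular statistic is best on real tissue data.

## Evaluation and cross-method aggregation

`recognition_rate()` is the fraction of replicates in which the causal set
ranks first after the FDR-then-NAS sort; `gsa_power()` the fraction with
causal p-value strictly below 0.05. Residual rank ties after FDR and NAS
are broken by set name so that replicate evaluation is deterministic.

`aggregate_ranks()` combines several methods' result tables the way the
case studies do: each method contributes its top-30 pathways with their
ranks, a pathway's NOC is the number of methods listing it, and pathways
listed by at least four methods are ordered by the average of their
non-zero ranks. The display convention rounds the average to two decimals;
internal ordering uses full precision.

## Numerical choices and degenerate inputs

* Empirical set p-values use the plain fraction over $N$ permutations with
  ties in the tail — the formula the significance machinery defines — so a
  set can have $p = 0$; the per-gene p-values use the pooled $N+1$
  convention above and cannot.
* Gene p-values are clamped at $1/(10N)$ before logarithms in the Fisher
  and geometric-mean statistics; under the pooled convention the clamp is
  inactive, but it keeps those statistics finite for user-supplied
  p-values.
* A null group with zero mean (or an empty same-sign group for the KS
  statistic) makes NAS undefined; it is reported as 0 with a warning.
* Sets covering every measured gene are rejected (the KS miss penalty is
  undefined); empty post-filter collections are an error in `run_gsa` and
  a warning in `filter_gene_sets`.
* Permutations are drawn in ID-sorted canonical sample space and mapped to
  file positions, so reordering input columns together with their labels
  reproduces results exactly, not just in distribution.

## Calibration

With zero DE genes, every set is null and set-level p-values should be
uniform. The test suite verifies, over 20 replicates of the full design
analysed with all ten statistics at $N = 2000$ (the permutation depth of
the simulation studies), that the fraction of sets with $p < 0.05$ lies
within $0.05 \pm 0.02$ for every statistic. The permutation depth matters
for one statistic: the minimum-p statistic takes values on the
$(N+1)$-point grid of empirical gene p-values, and when the grid is coarse
relative to the largest sets (e.g. $N = 200$ against 100-gene sets) its
tie-heavy ≤-tail p-values become over-conservative. This is a discreteness
artifact that vanishes at the depth real analyses use.

## Problem sizes used in the checks

Benchmarks in the test suite and the acceptance script run at a reduced
scale chosen to keep full runs reproducible on a single CPU in minutes: 50
replicates per scenario and 200 permutations per run for recognition
rates (the calibration check above uses 20 replicates at $N = 2000$).
Recognition rates at this scale are slightly noisier than at 200
replicates × 2000 permutations but estimate the same quantities; the
strong-signal scenarios (S5, S6) are expected at or very near 1.

## Known limitations

* Two phenotype classes only; no covariates, no continuous phenotypes.
* The gene-permutation mode ignores gene–gene correlation, and its
  per-gene p-values are cross-gene tail probabilities; it exists for
  comparison with list-based approaches, not as the recommended mode.
* FDR estimates are not monotonized; neighboring sets can have slightly
  inverted FDRs.
* Negative-binomial likelihood gene tests (DESeq/edgeR style) are outside
  the scope of this package's statistics.
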