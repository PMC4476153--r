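---
title: "Methods: correlated evolution of gene expression among genomic neighbors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: correlated evolution of gene expression among genomic neighbors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question and the model

Under a gene-centric view of regulatory evolution, a change in one gene's
expression says nothing about its neighbors. Chromatin-level control
suggests otherwise: opening or closing a chromosomal domain should move
spans of genes together, so the evolutionary change of a focal gene should
predict that of its neighbors — expression "piggybacking". This package
quantifies per-gene expression change on the human lineage and tests
whether that change is spatially organized along chromosomes.

Expression change is measured against the human–chimp ancestor. Per gene,
tissue and sex, the species mean expression values of human, chimp,
gorilla, orangutan and macaque are treated as tips of a Brownian-motion
(BM) trait model on a fixed time tree (`primate_tree()`; branch lengths in
My, human–chimp split at 6.7 My, root at 29 My). Under BM with root state
$\mu$ and rate $\sigma^2$, tip values are jointly Gaussian with
$\mathrm{cov}(x_i, x_j) = \sigma^2 t_{ij}$, where $t_{ij}$ is the shared
root-to-MRCA path length. The root mean is the GLS estimate, the rate is ML
(REML by flag), and the ancestral state at the human–chimp node has the
conditional-Gaussian posterior

$$E_a = \hat\mu + c^\top C^{-1}(x - \hat\mu\mathbf{1}), \qquad
  V_a = \hat\sigma^2\left(c_{aa} - c^\top C^{-1}c +
        \frac{(1 - \mathbf{1}^\top C^{-1}c)^2}{\mathbf{1}^\top C^{-1}\mathbf{1}}\right),$$

with $c$ the node–tip covariances (unit rate). The last term propagates the
uncertainty of the estimated root mean into $V_a$; we include it by default
because with only five tips the bare Schur complement is materially
anti-conservative (`mean_uncertainty = FALSE` recovers it). Two further
calibration facts drove the defaults:

* **Per-gene rates are extremely noisy.** Five tips leave ~4 degrees of
  freedom, so nominal 95% intervals built from per-gene rates behave like
  $t_4$ intervals (~88% coverage). `ancestral_table(rate = "pooled")`
  shares one REML rate across genes (in the spirit of variance moderation
  in expression analysis) and restores ~95% coverage when genes share a
  rate, as the synthetic generator's do. The default z-table pipeline keeps
  per-gene ML rates, mirroring how such data are usually processed; the
  pooled option is used wherever calibrated intervals matter.
* **The MCMC prior must be a scale prior.** `mcmc_ancestral()` samples
  $(\mu, \sigma^2, x_a)$ with a flat prior on $\mu$ and a flat prior on
  $\log\sigma^2$. A flat prior on $\sigma^2$ itself leaves the five-tip
  rate posterior inverse-gamma with shape 1 — infinite mean — and the
  node-state estimate without a finite Monte Carlo variance. The sampler
  draws $\mu$ and $x_a$ from their exact Gaussian conditionals and only
  $\log\sigma^2$ by random-walk Metropolis; estimates use the final 10% of
  the chain (`final_fraction = 0.10`), the retention rule used with long
  trait-MCMC runs, and a split-half convergence check is logged, not
  enforced. The MCMC marginal $V_a$ exceeds the plug-in analytic $V_a$
  (typically ~2x here) because it integrates over rate uncertainty; $E_a$
  agrees to Monte Carlo error.

## The divergence score

$$Z = \frac{E_c - E_a}{\sqrt{V_c + V_a}}$$

where $E_c$, $V_c$ are the human replicate mean and unbiased variance
(single replicates get $V_c = 0$ and a flag — the female strata have one
sample each). $Z$ is invariant to uniform rescaling of the expression unit
and, because it measures change from the ancestor, largely cancels
amplification biases shared by human and chimp. Within each tissue × sex,
`Z_mod = Z − median(Z)` encodes the assumption of no net transcriptome
size change; every downstream statistic is rank-based, so this is
presentation only. Conventions for degenerate cases:

* $V_c + V_a = 0$ with $E_c \ne E_a$: signed-infinity sentinel, flagged
  `degenerate`, excluded from all rank statistics.
* $E_c = 0$ with $E_a \le 0$ (no expression): flagged `zero_flag`
  ("too indecisive"), excluded from medians, correlations and sign
  sequences by default; a retain switch keeps them.
* Fold change $E_c / E_a$ is undefined (flagged, not raised) at
  $E_a \le 0$.

Expression-profile summaries apply a 2-RPKM floor (sub-floor tissues are
set to 0) before breadth, mean rate, peak rate and the specificity index
$\tau = \sum_j (1 - \log e_j / \log e_{max}) / (n-1)$. Zero-expression
tissues contribute their limit term 1 (maximally "off"); the log base
cancels.

## Spatial statistics and their conventions

* **Neighborhoods.** "Downstream" is by increasing published-strand
  coordinate, never gene orientation. Distance is either the body gap
  (bases strictly between gene bodies; the default) or start-to-start —
  both appear in practice and results are robust to the choice, so it is a
  config enum. The neighborhood radius and maximum gap default to 100 kb,
  the estimated span of the chromatin "ripple" effect. Nearest-neighbor
  and flanking-pair analyses use non-overlapping pairs (overlapping pairs
  are analyzed separately — they are the strongest-coupled class); window
  analyses drop focal genes overlapping an adjacent gene but keep
  overlapping non-focal neighbors. Start ties break deterministically by
  end then id.
* **Coordinates.** Gene tables are 1-based inclusive; BED interval sets
  are 0-based half-open. The conversion lives in one place
  (`gene_interval_overlap()`) and is tested against per-bp enumeration.
  Touching spans (gap 0) do not overlap.
* **Runs and edges.** Zeros are removed; a chromosome's +/− sequence is
  decomposed into maximal runs; the edge count is compared with
  within-chromosome permutations (preserving per-chromosome sign counts),
  one-tailed for fewer edges. Cluster-size spectra report per-size
  empirical P values (as-many-or-more direction).
* **Monte Carlo.** All empirical P values are $(N+1)/(M+1)$; all
  randomized procedures take and record seeds. Decay envelopes are mean ±
  1.96 SD over label shuffles, genome-wide by default (a per-chromosome
  flag exists). Subset comparisons are one-tailed "greater", matching
  their use as enrichment tests. Spearman P uses the t approximation above
  n = 10 and the exact distribution below; Bonferroni is pure
  post-processing with the family size recorded.
* **Cross-tissue.** Z sums use the six male tissues by default (more
  replicates). The concerted-cell expectation under independence is the
  product of per-tissue sign proportions. The Z-sum histogram is tested
  against column-wise sign permutations; because the expected histogram is
  itself estimated from the randomizations, the calibrated P is the
  empirical one (each null histogram's chi-square against the same
  expectation), with the asymptotic df = 2k tail reported alongside.
  Concerted-cluster runs are broken by any intervening non-concerted gene
  (a switchable convention). TSU uses Z > 1 in exactly one tissue, strict
  (≤ 0 elsewhere) and relaxed (< 1 elsewhere) variants; the across-tissue
  statistic sums per-tissue two-cell deviations with df = k − 1 and also
  reports per-tissue P values and their Fisher combination.
* **Sex bias.** Change in sex bias is the standardized residual from the
  standard major axis fit of female on mean male Z (slope
  $\mathrm{sign}(r)\,SD_y/SD_x$). The vertical deviation is standardized
  to unit SD; a signed-orthogonal variant differs only by a monotone
  rescale, so rank statistics are identical. Residuals are standardized
  per tissue. X-vs-autosome contrasts use Mann–Whitney on the modulus and
  a 2×2 chi-square on the top-5% tail (tail size exactly
  $\lceil 0.05 n \rceil$).

## The synthetic-data generator

`sim_config()` defaults emulate the target data regime: 13,027 genes on 22
autosomes plus chrX, six tissues, five species, three male replicates and
one female, female liver/testis absent (absent columns, never zeros).
Expression evolves on a log scale (BM stays Gaussian while RPKM-like
outputs stay non-negative after exponentiation), with root states
N(1.5, 1) in log units, rate 0.05 /My (root-to-tip SD ≈ 1.2 log units,
a realistic cross-primate spread), replicate noise 0.25 log units, and a
5% chance a gene is silent in a tissue (exercising the zero-Z path).
Human-branch shifts are shared by contiguous blocks of 10 genes (blocks
never span chromosomes), hit a block with probability 0.2 at scale 1.0 log
units, and 30% of shifted blocks are "concerted" (one sign across all
tissues). Optional female-specific block shifts support sex-bias power
studies. Annotation tracks (LAD-like, peak-like, gained/depleted peak
sets, hmC/mC-like scalars) couple to the true shifts through one signed
strength; at coupling 0 they are exactly independent of the truth.

What the generator does **not** emulate: read-level sampling,
GC/amplification bias (the Z construction cancels such biases by design),
unequal per-species replication, isoform structure, and realistic
clustered gene-density landscapes (gaps are exponential with a 60 kb mean
— a gene-dense regime chosen so sub-100 kb neighbor pairs are plentiful).
Passing tests therefore demonstrate internal statistical correctness and
power against the planted mechanism, not robustness to every artifact of
real RNA-seq.

## Problem sizes used by the checks

The recovery check runs 500 genes × 6 tissues under the generator's null
(`shift_prob = 0` — shifts are deliberate model violations planted for the
spatial statistics, so the estimator is calibrated under its own model),
with the pooled rate; MCMC agreement uses 20 genes at 2×10⁴ iterations.
Type-I calibration uses 200 seeds of 300-gene genomes; the power check
uses 100 seeds of 2,000-gene genomes with 40% of blocks shifted at scale 3
log units ("strong" shifts, ~20-fold expression change, chosen so planted
sign runs survive drift and noise at the sign level) and 199-permutation
nulls; the decay check uses one 400-gene genome with an ~800 kb block span
and a [1 bp, 3 Mb] grid.

## Known limitations

* The BM model ignores measurement error in the tips; with the default
  noise settings this inflates the pooled rate slightly and (by partial
  cancellation) leaves interval coverage near nominal, but heavy-noise
  regimes would need an explicit error term.
* Raw-scale (RPKM) BM fitting — the conventional choice the default
  pipeline mirrors — can produce negative ancestral means for weakly
  expressed genes; these surface only through the flagged fold-change and
  zero-Z conventions.
* Per-gene rate estimates from five tips are noisy by construction; the
  pooled option trades bias for calibration and assumes rate sharing.
* The orientation, overlap and window analyses treat each gene as a single
  span; isoform-level overlap is out of scope.
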