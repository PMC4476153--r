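# neighborz

Tools for asking whether evolutionary change in gene expression is
genomically clustered — whether, when one gene's expression rises or falls
along a lineage, its chromosomal neighbors tend to change with it
("expression piggybacking", the expression analog of genetic hitchhiking).
The package is aimed at evolutionary and comparative genomicists working
with multi-species, multi-tissue expression compendia such as the
five-primate, six-tissue RPKM datasets.

## The statistic at the core

For each gene in each tissue and sex, the current human expression level is
summarized as a replicate mean `E_c` with sampling variance `V_c`, and the
expression level at the human–chimp ancestor is reconstructed under a
Brownian-motion trait model on the primate time tree, giving a posterior
mean `E_a` and variance `V_a` (closed-form conditional Gaussian by default;
an MCMC sampler reproduces it). Expression divergence is then

```
Z = (E_c − E_a) / sqrt(V_c + V_a)
```

i.e. change since the ancestor in standard-deviation units, discounting both
measurement noise and reconstruction uncertainty. Within each tissue × sex
stratum, `Z_mod = Z − median(Z)` forces a zero median of change (no net
transcriptome growth); all downstream statistics are rank-based, so the
correction never alters them.

Around this score the package provides the full battery of spatial and
comparative statistics: neighbor correlations (nearest downstream neighbor,
flanking pair, or all neighbors within 100 kb), sign-run / edge-count
randomization tests and cluster-size spectra, distance-decay correlograms
with 1.96-SD Monte Carlo envelopes, cross-tissue concertedness (Z sums,
independence nulls, concerted-cluster scans), tissue-specific upregulation
tests, chromatin-mark overlap chi-squares and scalar-track correlations,
standard-major-axis residual analyses of sex-biased change, and
X-chromosome contrasts. A synthetic-data generator with known ground truth
(Brownian evolution plus block-shared human-branch shifts on a
chromosome-ordered gene map, with coupled annotation tracks) supports
calibration and power analysis of every test. Throughout, Monte Carlo
significance is the unbiased estimate `P = (N+1)/(M+1)`.

## Worked example

```r
library(neighborz)

tree <- primate_tree()                      # 5-taxon time tree, node "hc"
cfg  <- sim_config(n_genes = 1000, n_chromosomes = 5,
                   shift_prob = 0.3, shift_sd = 2, seed = 7)
map  <- generate_gene_map(cfg)
sim  <- simulate_expression(map, cfg)       # dataset + ground truth
zt   <- compute_z_table(sim$dataset, tree)  # per gene/tissue/sex Z table

head(zt[zt$tissue == "brain" & zt$sex == "male",
        c("gene", "E_c", "E_a", "V_a", "Z_mod", "sign")], 3)
#>     gene       E_c       E_a       V_a      Z_mod sign
#> 1 g00001  2.786104  6.374364  6.421558 -0.9349060   -1
#> 2 g00002 25.691200 29.721543 16.004677 -0.4615409   -1
#> 3 g00003  1.645809  4.298535  8.285353 -0.5737021   -1

z <- setNames(zt$Z_mod[zt$tissue == "brain" & zt$sex == "male" & !zt$zero_flag],
              zt$gene[zt$tissue == "brain" & zt$sex == "male" & !zt$zero_flag])
neighbor_correlation(z, map, mode = "downstream")
#> Spearman rho = 0.3933949, P = 1.165463e-27, n = 709

sub <- map[map$gene %in% names(z), ]
run_randomization_test(sign(z[sub$gene]), sub$chrom, n_rand = 999, seed = 1)
#> Monte Carlo: observed 364, null 473.1532 +/- 14.85034,
#>   empirical P (less) = 0.001 [N=0, M=999]
```

The simulated data carry block-shared human-branch shifts (blocks of 10
genes, 30% of blocks shifted), so focal and neighbor Z scores correlate
strongly (rho 0.39 over 709 non-overlapping downstream pairs within
100 kb), and the genome shows far fewer sign switches along chromosomes
(364) than its within-chromosome permutation null (473 ± 15) — the
clustering signature the pipeline is built to detect. Under
`shift_prob = 0` both statistics are calibrated null results.

## Documentation

The methods vignette (`vignettes/expression-piggybacking.Rmd`) describes
the model and its assumptions, every tunable constant (the 100 kb
neighborhood, the 2-RPKM expression floor, the Z > 1 tissue-specificity
cutoff, chain retention), what the synthetic generator does and does not
emulate, and known limitations.
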