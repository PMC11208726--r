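---
title: "LD-aware genotype compression with per-block autoencoders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{LD-aware genotype compression with per-block autoencoders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Dense SNP panels carry millions of variants per individual, far more than
any downstream model can digest, and most of that width is redundant:
nearby variants travel together on shared haplotypes (linkage
disequilibrium, LD). `haploae` compresses a genotype matrix by (i)
partitioning each chromosome into haplotype blocks — contiguous stretches
whose variant pairs show strong LD — and (ii) training one small
autoencoder per block to squeeze the block's dosage columns into a two- or
three-dimensional embedding. Because the compressor is non-linear, it can
retain joint (potentially epistatic) allele patterns that a variance-based
linear projection discards; a matched-dimension PCA baseline is built in
so that claim can be tested rather than assumed.

## Pipeline and model

### Input representation

Genotypes enter as a samples x SNPs matrix of minor-allele dosages
(0/1/2). `read_vcf()` converts VCF GT fields into ALT counts;
`filter_missing()` drops every variant with a non-zero missing rate;
`additive_recode()` orients each column to the minor allele (a column
whose counted allele has frequency above 0.5 is flipped entry-wise,
`d -> 2 - d`); `filter_maf()` keeps common variants (MAF strictly above
0.01 by default). A frequency of exactly 0.5 is left as the ALT allele —
an arbitrary but deterministic convention.

### Haplotype blocks from D' confidence intervals

For every variant pair within a scanning window we estimate the four
two-locus haplotype frequencies from unphased genotypes with an EM
(uniform start; only the double heterozygote is ambiguous; convergence at
a maximum frequency change of 1e-7 or 1000 iterations), then profile the
genotype likelihood over a 101-point grid of D' values in [0, 1] with
allele frequencies held at their sample estimates. Normalizing that
profile to a unit mass yields equal-tail 90% bounds `(ci_low, ci_high)`.
Pairs are classified as

* **strong LD** — `ci_low >= 0.5` and `ci_high >= 0.85`,
* **strong historical recombination** — `ci_high < 0.7`,
* **non-informative** — anything else, including pairs with a monomorphic
  locus.

A candidate block is a contiguous index run whose outermost pair is itself
strong-LD and whose span is at most 10 Mb; it is accepted when strong-LD
pairs make up at least 95% of its informative pairs. Accepted candidates
are chosen greedily by SNP count (leftmost start on ties) without overlap.
These thresholds (0.5/0.85 interval, 0.7 recombination bound, 10 Mb
window) are the calibrated setting this package standardizes on; all are
adjustable through `block_config()`. The 101-point grid, the 90%
confidence level and the 0.95 informative fraction follow the Haploview
convention; small-sample shortcut tables are deliberately not
special-cased — the full likelihood interval is always computed, which is
simpler, testable, and asymptotically equivalent. SNPs in no block are
kept as explicit singletons and passed through uncompressed.

`average_pairwise_ld()` summarizes a block's internal variation as the
mean pairwise r² (the squared allelic correlation); D' averaging is
available behind a flag but r² is the default because it is the measure
used for pruning decisions in practice.

### The autoencoder family

Each block's autoencoder is fully described by `(input_dim, hl, bn,
shape)`. Widths follow

```
n(l) = bn + (input_dim - bn) * (|l| / (hl + 1))^p,   l = -(hl+1), ..., hl+1
```

rounded to the nearest integer with halves away from zero; `n(0) = bn` and
`n(±(hl+1)) = input_dim` hold exactly. `p = 0` gives the rectangular
profile (all non-bottleneck layers input-wide), `p = 0.5` the elliptic
taper. The network therefore has `2*hl + 3` layers. Hidden layers use a
leaky rectified linear activation (negative slope 0.01, a common default;
the original description leaves it open) and He-uniform initial weights;
the output layer uses `r(x) = tanh(x) + 1`, whose open range (0, 2)
matches the dosage scale, so raw dosages are fed without rescaling.

Training is minibatch Adam on the mean squared reconstruction error: 50
epochs, batch size 32, learning rate 1e-4, samples reshuffled each epoch
from a per-block stream derived from `(seed, block_id)` — so a panel's
results do not depend on block processing order, and identical seeds
reproduce identical weights. There is no early stopping, learning-rate
schedule or weight decay: the recipe is deliberately fixed so that tens of
thousands of block models need no per-block tuning. All of it is
overridable through `train_recipe()`.

Two metrics are reported per block: the reconstruction MSE and the SNP
accuracy — predictions rounded to the nearest dosage (halves up, clamped
to 0..2) and compared entry-wise, also broken down by true dosage value
(0s, 1s, 2s) and by phenotype group when labels exist. The compression
ratio is `bn / input_dim`; chromosome-wide, total compressed width over
total SNPs, and the chromosome reconstruction accuracy is the
block-size-weighted mean of per-block accuracies, identical to pooling
every per-variant indicator.

### Choosing the architecture

`grid_search_block()` reproduces the tuning protocol: bn 1–10, hl 1–5,
both shapes, under 5-fold cross-validation with shared fold assignments,
ties broken toward fewer hidden layers and the elliptic shape (cheaper
models first). `elbow_point()` formalizes the compression/accuracy
trade-off as the smallest bn whose marginal accuracy gain falls below
0.002 — a threshold chosen to bracket the scale at which an extra
bottleneck dimension stops paying for itself. The standardized outcome is
encoded in `selection_rule()`: elliptic shape, four hidden layers, and
bn = 2 for blocks whose average pairwise r² exceeds 0.4 (low internal
variation) or bn = 3 otherwise; exactly 0.4 takes the wider bottleneck.
Blocks no wider than their assigned bn, and singleton SNPs, are passed
through uncompressed with ratio 1. `paired_one_tailed_ttest()` supports
the significance comparisons that justify collapsing the grid to this one
configuration; zero-variance difference vectors are flagged degenerate and
reported as not significant rather than inflating a t statistic.

### PCA baseline

`fit_pca()`/`pca_reconstruct()` provide the linear control at matched
latent dimension: the top-k principal directions of the centered training
block, with held-out samples centered by the training means. Linear
reconstructions are clipped to [0, 2] before rounding so both methods
share the accuracy operation's domain (an unclipped mode exists for
sensitivity checks; whether to clip is genuinely open, and clipping never
hurts the baseline). No column scaling is applied — dosages share a scale.

## The synthetic data generator

Real cohort genotypes at this scale are access-restricted, so the package
ships a founder-haplotype simulator that instantiates exactly the
structure the method exploits: a block carries K founder haplotypes
(binary vectors; each SNP's minor allele is assigned to a uniformly random
founder subset), every individual draws two founders i.i.d. from the
founder distribution (a symmetric Dirichlet draw with concentration 2 by
default — mildly unbalanced, never degenerate), and each inherited allele
flips with probability ε. Dosages are the allele sums; columns below the
MAF floor (0.05 by default, comfortably above the 0.01 filter) are
redrawn. K and ε map directly onto the internal-LD axis: K = 2–3 blocks
are in near-complete D' (at most three gametes exist), while K ≥ 4 admits
four-gamete pairs and hence genuine recombination signal; ε erodes r²
monotonically. `calibrate_ld()` tunes (K, ε) by bisection to hit a target
average r², pinning founder frequencies to uniform so the calibrated
structure transfers across seeds.

The default chromosome-scale fixture (`standard_panel_config()`) mimics a
realistic block-size landscape at reduced size: 50 blocks, log-normal
sizes with mean ~25 SNPs (positively skewed, like real block-size
distributions), K drawn uniformly from 2–6, ε from U(0.001, 0.01), 2000
samples. What the generator does **not** emulate: population structure
and relatedness, rare variants, genealogically nested founder patterns
(real haplotypes are related by descent, which concentrates LD higher
than uniform random founder subsets at the same K), and structured
genotyping error. Tests passing on these panels therefore demonstrate the
machinery and its contracts, not performance on any particular cohort.

## Numerical choices

* Width and prediction rounding: halves away from zero ("nearest"
  otherwise under-specifies the rule).
* EM: uniform start, tolerance 1e-7 on frequencies, 1000-iteration cap;
  the log-likelihood is non-decreasing by construction and tested.
* D' CI: likelihoods are normalized by their maximum before
  exponentiation; zero haplotype frequencies are floored at 1e-300 inside
  logs only.
* Degenerate pairs (monomorphic locus) are non-informative, never errors.
* Greedy block selection ties: leftmost start.
* Adam: beta1 0.9, beta2 0.999, epsilon 1e-8.
* PCA latent dimension is capped at `min(bn, n_train - 1, block width)`.
* Train/test splits are by explicit sample-id lists (mirroring a held-out
  stratum) or a seeded random fraction; held-out samples never reach any
  optimizer or PCA fit, and the pipeline asserts the split is disjoint.

## Problem sizes and what to expect at them

The test suite and the bundled `scripts/acceptance.R` run the full
pipeline on panels of 50 blocks x ~25 SNPs x 2000 samples (and 30
eight-founder blocks for the PCA comparison) — sizes chosen so a complete
run finishes in minutes on one core. Two consequences of that scale are
worth understanding when reading results:

* **Optimizer budget.** The fixed 50-epoch/batch-32 recipe performs a
  number of Adam steps proportional to the sample count. At 1600 training
  samples that is 2500 steps per block — enough for two- and
  three-founder blocks (which reach perfect or near-perfect held-out
  accuracy) but visibly short of convergence for high-variation blocks
  (K ≥ 5, average r² below ~0.3), where accuracy keeps improving for
  hundreds of further epochs. The recipe is kept fixed because it is the
  method's standardization contract; the vignette's test results should
  be read as the scaled-down operating point of that contract, not its
  asymptote. Property tests that probe *attainable* accuracy (e.g.
  bottleneck-width monotonicity) therefore override the recipe with a
  longer schedule.
* **Noise floor.** A per-allele flip rate ε caps achievable held-out
  accuracy near `1 - 2ε` per entry: flipped alleles are independent of
  haplotype structure and cannot be predicted from a bottleneck. At the
  generator's default ε range this floor sits around 99%.

## Limitations

* Block detection is O(pairs) in compiled code but the span-acceptance
  bookkeeping holds two m x m matrices per chromosome; panels beyond a
  few thousand SNPs per chromosome should be processed in windows.
* Haploid calls (chrX males), multi-allelic sites and imputation are out
  of scope; inputs are diploid biallelic autosomal genotypes.
* Exact agreement with other block-finder implementations on edge cases
  is not guaranteed: published implementations add small-sample CI
  shortcut tables that this package intentionally replaces with the full
  likelihood interval.
* The trainer is plain R matrix algebra: ideal for blocks of tens of
  SNPs, not for networks orders of magnitude larger.
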