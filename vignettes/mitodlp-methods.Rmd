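---
title: "Methods: single-cell mtDNA copy number, heteroplasmy and clonal inference"
author: "mitodlp authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell mtDNA copy number, heteroplasmy and clonal inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitodlp)
```

# Scope and model

`mitodlp` analyses amplification-free single-cell whole-genome sequencing
(scWGS), in which each cell's library is prepared without PCR
pre-amplification. Because mtDNA is present in hundreds to thousands of
copies per cell while the nuclear genome is present in a handful, the
ratio of mean mtDNA read depth to mean nuclear read depth is directly
interpretable as a copy-number ratio. The package implements four
connected analyses and a synthetic-data generator that emulates the data
they assume.

## Copy number and MNR

For each cell,

$$\mathrm{CN} = \frac{\text{mtDNA depth}}{\text{nuDNA depth}} \times
  \text{average ploidy}, \qquad
  \mathrm{MNR} = \frac{\text{mtDNA depth}}{\text{nuDNA depth}},$$

where average ploidy is the arithmetic mean of per-bin integer nuclear
copy-number states over 500-kb bins (provided as input; segmentation is
upstream of this package), and baseline ploidy is the modal bin state,
used to label cells diploid/triploid/tetraploid. The two ploidies are
kept distinct deliberately: the CN formula needs the average (arm-level
gains shift it off the integer), while whole-genome-doubling (WGD)
labels need the mode. Ties in the mode go to the *smallest* tied state,
a conservative choice against over-calling WGD. Depths are mean
per-base coverages, not read counts, which removes read-length
dependence; CN is therefore invariant to rescaling both depths by a
common factor.

The MNR is the quantity expected to be homeostatic under WGD: doubling
the nuclear genome roughly doubles the mtDNA complement, so CN doubles
while MNR is preserved. `mnrPercentChange()` quantifies departures as
$100\,(\mathrm{median}(\mathrm{MNR}_t) -
\mathrm{median}(\mathrm{MNR}_d))/\mathrm{median}(\mathrm{MNR}_d)$, and
`ploidyContrast()` runs Wilcoxon rank-sum tests per sample (two-sided
for CN, one-sided tetraploid > diploid for MNR by default, matching the
directional homeostasis question; both alternatives are configurable).
Base R's `wilcox.test` switches to its normal approximation in the
presence of ties, so exact p values are only reported for untied
groups.

## Variant filter stack

Input is pileup-level, strand-split allele counts per (cell, variant),
assumed already filtered to mapping quality > 20 and base quality > 20
upstream. Three filters are applied; each is a property of the variant
alone, so the stack is order-invariant, and a variant is PASS iff it
passes all three:

* **Pooled strand support** — at least 2 alternate reads on each strand
  in the pseudo-bulk over quality-passing cells. Strand-exclusive
  evidence is the signature of a mapping artifact.
* **Strand concordance** — Pearson correlation of per-cell forward and
  reverse heteroplasmy, over cells with coverage on both strands, must
  reach $R \ge 0.2$. A correlation that is undefined (fewer than 3
  informative cells, or zero variance on a strand) fails conservatively
  with a reason code; the 3-cell floor is this package's choice of the
  smallest sample for which a correlation is meaningful.
* **Blacklist** — positions within the homopolymer repeat regions
  513–525 and 3105–3109 (1-based, inclusive both ends, rCRS-style
  coordinates on the circular contig) are removed.

Per-cell heteroplasmy is the strand-pooled ratio
$(f_{alt}+r_{alt})/(f_{tot}+r_{tot})$, missing where the denominator is
zero. Variants with median defined heteroplasmy above 0.95 are labelled
homoplasmic; this operationalizes the homoplasmic/heteroplasmic split
without haplogroup inference, which is out of scope (it requires an
external haplogroup database). Trinucleotide substitution spectra are
computed with circular wrap-around, normalized by the reference
frequency of each context, reported separately for the reference (L)
strand and its reverse complement (H); de-normalizing and summing
recovers the substitution totals. Homopolymer length heteroplasmy at an
anchor (e.g. the poly-C block at m.302) is the per-cell
reference-allele fraction among cells with at least 10 reads at the
anchor.

## MityBayes: binomial-mixture clonal inference

Given alternate counts $a_{cv}$ and totals $n_{cv}$, cells are assigned
to $K$ clones under
$a_{cv} \mid z_c = k \sim \mathrm{Binomial}(n_{cv}, P_{kv})$ with clone
fractions $\pi$ and priors $\pi \sim \mathrm{Dirichlet}(\alpha)$,
$P_{kv} \sim \mathrm{Beta}(a, b)$. The fit maximizes the MAP objective

$$\sum_c \log \sum_k \pi_k \prod_v
  \mathrm{Binom}(a_{cv} \mid n_{cv}, P_{kv}) + \log p(\pi) + \log p(P)$$

with assignments marginalized; the posterior assignment matrix
$\gamma$ holds the responsibilities at the optimum. Two backends
optimize the identical objective:

* **EM** (default): closed-form M-steps; the objective is provably
  nondecreasing, which the tests assert exactly.
* **Gradient**: ascent in unconstrained coordinates (softmax for
  $\pi$, logit for $P$) with backtracking line search starting from
  step size `lr = 0.1`. Backtracking keeps this backend monotone too;
  a point-mass (MAP) variational treatment of this model reduces to
  exactly this optimization, so the two backends are required by the
  test suite to agree on the objective and the partition.

Numerical choices: $P$ is clipped to $[10^{-6}, 1-10^{-6}]$ for finite
log-likelihoods; convergence is a relative objective change below
$10^{-5}$; 8 restarts by default (the first warm-started by k-means on
the observed heteroplasmy, the rest from random hard partitions), all
seeded from the master seed, with the best objective kept. Priors
default to flat Beta(1,1)/Dirichlet(1); `mbPriors(fixedPi = ...)`
instead holds the clone fractions fixed, covering both readings of a
"prior on the number of clones" — a fixed K is the supported intent,
and `selectK()` adds a BIC-style search
($-2\,\mathrm{objective} + p\log C$, $p = (K-1) + KV$) when K is
unknown, returning the full table so the user can override.

`exactPosterior()` is the package's own oracle: on instances of at most
8 cells, 4 variants and 3 clones it enumerates every assignment,
profiles $P$ over a 0.01-spaced grid (with its Beta prior) and $\pi$ at
its per-assignment MAP, and returns the global MAP assignment and exact
marginals. By default the enumeration is over labelled assignments, so
symmetric instances yield uniform marginals — the correct exact answer;
`canonical = TRUE` enumerates each partition once for direct comparison
with a fitted model after label alignment. Tie-breaking in
`assignClones()` is by lowest clone index; cells whose maximum
probability is below `minProb` stay "unassigned". Variant contribution
weights measure, per variant, the posterior-averaged log-likelihood
gain of clone-specific heteroplasmy over the pooled rate, min-max
rescaled to $[0,1]$; in the fully degenerate case where every variant
scores equally, all weights are set to a common value (1 if the common
score is nonzero, else 0).

## Stratified weighted concordance

Association between a variant's heteroplasmy $h$ and per-cell CN $y$ is
measured nonparametrically. Within each stratum (sequencing library),
every observation pair is concordant if $(h_i-h_j)(y_i-y_j) > 0$,
discordant if $< 0$, tied otherwise;
$c_s = (\text{concordant} + 0.5\,\text{ties})/\text{pairs}$. Strata are
combined with weights $w_s$ equal to the number of cells in the
library: $c = \sum_s w_s c_s / \sum_s w_s$. With one stratum and no
ties, $2c - 1$ equals Kendall's tau-a exactly (a property the tests
verify against base R's Kendall correlation), and the statistic is
invariant to strictly monotone transforms of either variable.

For the null variance we map the classical Kendall null variance to the
concordance scale, $\mathrm{Var}_0(c_s) = \frac{2(2n_s+5)}{9 n_s
(n_s-1)}/4$, and combine as $\sum_s w_s^2 \mathrm{Var}_0(c_s) / (\sum_s
w_s)^2$; then $z = (c - 0.5)/\sqrt{\mathrm{Var}}$ with a two-tailed
normal p value. This concrete variance is this package's design; its
calibration is arbitrated by `permutationNull()`, which permutes $y$
within strata and must agree with the analytic p within Monte-Carlo
error — the tests additionally check that the type-I error at
$\alpha = 0.05$ lies in $[0.03, 0.07]$ under simulated independence.

Observation filters before the test: at least 10 alternate reads per
cell-variant observation (the stricter per-cell reading of the
alternate-read threshold, configurable), heteroplasmy window dropping
$h < 0.05$ or $h > 0.95$ (endpoints retained, read literally), and a
minimum surviving range of 0.15 (inclusive). Multiple testing uses
Benjamini–Hochberg via `stats::p.adjust` behind `bhAdjust()`. Cell-size
association uses per-library OLS of CN on diameter (and on diameter
plus average ploidy), Pearson correlation with BH across libraries —
across libraries, not across cells, which is the reading adopted here
of an ambiguous correction family; a per-cell family made no sense for
a per-library statistic.

## Nuclear-profile clone calls

`clusterCellsNu()` assigns clones from nuclear bin-state profiles. The
embedding/density backend (UMAP with `min_dist = 0`, correlation
metric; HDBSCAN with `cluster_selection_epsilon = 0.2`,
`approx_min_span_tree = FALSE`, `gen_min_span_tree = TRUE`) is an
optional adapter — these are off-the-shelf algorithms, not this
package's contribution — and the dependency-free fallback used by the
test suite is average-linkage hierarchical clustering on correlation
distance with the cluster count chosen by mean silhouette width.
Correlation distance has a useful property here: a tetraploid cell's
profile is twice its diploid clone-mate's and thus at distance zero, so
WGD subpopulations cluster with their clone, as they should. Flat
(zero-variance) profiles, for which correlation is undefined, are
attached to the nearest clustered cell by Euclidean distance.
`crosscheckClones()` compares nuclear and mtDNA partitions by adjusted
Rand index (via `mclust`).

# The synthetic-data generator

`simulateDataset()` emulates the statistical structure the analyses
assume, with defaults chosen as the package's standing study
conditions: ~500 cells per library (a typical library size), MNR 378 so
that a diploid cell carries ~756 mtDNA copies (a typical lymphoblastoid
value), within-stratum copy-number coefficient of variation 0.65
(typical of single-cell mtDNA copy-number distributions), WGD in 13% of
cells, 79 reads per mtDNA site per cell, and a cell-size coupling of 24
mtDNA copies per micron around a 10 µm baseline with 1 µm Gaussian
noise.

Generative structure, per cell:

1. clone $\sim$ Multinomial(clone fractions); WGD $\sim$
   Bernoulli(per-clone fraction);
2. nuclear bin states equal the clone's diploid baseline profile,
   doubled exactly under WGD. With $K > 1$ every clone alters ~30% of
   bins by one state; bin states carry **no additional per-cell
   noise** — a deliberate simplification so that the noise-free limit
   (`cnCV = 0`, no WGD, one clone) yields CN exactly
   $\text{MNR} \times 2$, and so that clone recovery from profiles is a
   well-posed target. Real bin-state calls are noisier; the clustering
   ARI achieved on synthetic data is accordingly an upper bound on real
   data;
3. true CN $=$ clone MNR $\times$ average ploidy $\times$ lognormal
   noise with $\sigma = \sqrt{\log(1+\mathrm{CV}^2)}$ and unit mean —
   strictly positive and right-skewed, as empirical per-cell CN
   distributions are;
4. depths satisfy the estimator identity exactly
   (mt depth $=$ MNR $\times$ nu depth, nu depth lognormal around its
   mean), so copy-number error in pipelines comes only from the stages
   under test; the downsampling experiments re-introduce read-sampling
   noise explicitly by binomial thinning;
5. per-variant totals $\sim$ Poisson(coverage $\times$ CN / library
   mean CN) — deeper cells have more mtDNA reads; alternates $\sim$
   Binomial(total, clone heteroplasmy); strands split
   Binomial$(\cdot, 0.5)$, so strand-balanced truth. Optional
   injectors plant variants inside the blacklist regions and
   forward-only "strand artifact" variants (all reads on one strand)
   as negative controls for the filters.

What the generator does *not* emulate: sequencing error and base
substitution noise, NUMT contamination, doublets, GC bias, bin-level
segmentation error, and S-phase copy-number scaling. Passing tests
therefore demonstrate correctness of the statistical machinery under
its stated model, not robustness to those artifacts.

# Problem sizes used by the tests

The test suite and the acceptance script run entirely on synthetic
data at sizes chosen to make every Monte-Carlo bound comfortable:
recovery experiments use 200 cells × 10 variants × 3 clones at 50×
site coverage over 20 replicates; homeostasis checks use 2,000–4,000
cells; calibration uses 1,000 null replicates of 80 observations in
two strata; the enumeration oracle runs on instances up to 8 cells.
A full demo pipeline (200 cells, 2 clones) runs in a few seconds.

# Known limitations

* The concordance null variance is asymptotic; for strata under ~10
  observations the permutation p value is the better-calibrated choice
  (and is what the package recommends there).
* `selectK`'s BIC penalty treats every cell as one observation; with
  very low coverage it under-penalizes weakly supported extra clones.
* The homoplasmy threshold (median > 0.95) conflates germline variants
  with fixed somatic variants; distinguishing them requires haplogroup
  context that this package does not model.
* Diameters enter only as a covariate; no image processing is done.
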