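---
title: "Models and methods behind phyllogwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phyllogwas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`phyllogwas` turns a genotype matrix and per-sample microbial species
counts into community statistics, per-species mixed-model association
scans, merged loci, order-level locus clusters and pathway enrichment.
This vignette explains the models, the defaults, and the design decisions
where the methodology left genuine freedom.

## Traits from counts

Metagenomic species counts are compositional and heavy-tailed. The
pipeline first removes species whose average relative abundance across
samples does not exceed `min_mean_rel_abund` (default `1e-5`, i.e.
0.001%), then applies cumulative-sum scaling (CSS): for sample $j$, let
$q_j$ be the $l$-th quantile of its *nonzero* counts; the scaling factor
is $s_j = \sum_{i: c_{ij} \le q_j} c_{ij}$ and normalized values are
$c_{ij} / s_j \times N$. Quantiles use the linear-interpolation convention
(R's type 7) and are taken over nonzero counts only, so structural zeros
do not deflate $s_j$; this makes the factors invariant to per-sample
rescaling of counts, which is the property the normalization exists for.
Defaults are a fixed median quantile ($l = 0.5$) and $N = 1000$. An
adaptive-quantile CSS variant exists in the literature; we fix the median
because it is deterministic and easy to reason about, and expose `quantile`
as an argument.

The trait handed to the association scan is $\log_2(\text{CSS} + 1)$.
Whether GWAS traits should be CSS counts, relative abundances or
transformed values is a genuinely open choice; we default to the log2
transform because it symmetrizes the heavy right tail that otherwise
dominates least-squares fits, and record the choice in the output
metadata. `css_normalize(log2_transform = FALSE)` yields raw CSS values.

## Community statistics

Shannon diversity uses natural logs over nonzero proportions. Bray–Curtis
dissimilarity is $\sum_i |x_i - y_i| / \sum_i (x_i + y_i)$ (delegated to
`vegan::vegdist`; pairs of all-zero samples are rejected). PCoA is
classical metric scaling: eigendecomposition of the double-centered
$-D^2/2$. Negative eigenvalues — expected for non-Euclidean dissimilarities
— are reported but excluded from the explained-variance denominator; no
Cailliez correction is applied by default because it changes coordinates
for all samples, not only the offending axes. Axis signs are fixed so each
axis's largest-magnitude coordinate is positive, which makes ordinations
reproducible across platforms.

PERMANOVA uses the distance-based pseudo-F
$F = \frac{(SS_T - SS_W)/(a-1)}{SS_W/(n-a)}$ with
$SS_T = \sum_{i<j} d_{ij}^2 / n$ and within-group terms divided by group
sizes, which handles unbalanced groups. The p-value is
$(1 + \#\{F^{perm} \ge F\}) / (1 + n_{perm})$ — hence resolution exactly
$1/(n_{perm}+1)$, default 999 permutations — and an `exact = TRUE` mode
enumerates all $n!$ relabelings for $n \le 9$, which the test suite uses
to validate the permutation machinery.

Differential abundance offers both the Wilcoxon rank-sum test (normal
approximation with tie correction; exact enumeration automatically when
the combined group size is at most 10 and ties are absent) and one-way
ANOVA with Tukey's HSD (studentized range); both are standard in
phyllosphere comparisons and both are reported because either may be the
appropriate choice depending on distributional shape. BH adjustment runs
across taxa.

## The mixed model

Each species trait $y$ is scanned under
$y = X\beta + u + e$, $u \sim N(0, \sigma_g^2 K)$,
$e \sim N(0, \sigma_e^2 I)$, where $X$ holds an intercept and structure
covariates $Q$, and $K$ is the VanRaden (method 1) genomic relationship
matrix: dosages centered by $2p_k$ and
$K = ZZ^\top / (2\sum_k p_k(1-p_k))$. The construction of $K$ and the
source of $Q$ are configuration choices in most GWAS tools; we use
VanRaden because it is closed-form and testable (mean diagonal ≈ 1 under
Hardy–Weinberg), and default $Q$ to the top 3 genotype principal
components (configurable `q`, `q = 0` meaning no structure covariates).

With $\delta = \sigma_e^2/\sigma_g^2$ the covariance is
$\sigma_g^2 (K + \delta I)$; rotating by the eigenvectors of $K$
diagonalizes it with per-component variance $\lambda_i + \delta$. The REML
profile likelihood in $\delta$ is evaluated on a grid of 101 points over
$\log_{10}\delta \in [-5, 5]$ and refined by bounded one-dimensional
optimization between the neighbors of the best grid point; the grid guards
against multimodality, the refinement against grid coarseness. REML (not
ML) is used so variance components are unbiased by the fixed effects.

The scan uses the EMMAX/P3D approximation: variance components are
estimated once per trait on the null model and held fixed per SNP, which
is what standard mixed-model GWAS implementations do when scanning
thousands of traits — exact per-SNP REML would be prohibitive at
$6{,}862$ traits $\times$ $168{,}699$ SNPs scale and changes p-values
negligibly when single-SNP effects are small. Each SNP is tested by
weighted least squares on the rotated data (weights
$(\lambda_i + \hat\delta)^{-1/2}$), with the residual variance re-estimated
per SNP and $t = \hat\beta/se$ referred to $t_{n - \mathrm{rank}(X) - 1}$.
The test suite verifies this path against a dense explicit-GLS oracle
(direct inversion of $K + \delta I$) to $10^{-6}$ in $\log_{10} p$.

MAF filtering removes SNPs with MAF strictly below 0.05 (boundary kept),
computed on observed calls; missing dosages are mean-imputed afterwards
for kinship and scanning. SNPs constant after imputation are reported with
$p = 1$ and a `degenerate` flag rather than dropped, so row counts stay
predictable. No multiple-testing correction is applied across traits: the
pipeline's significance rule is the fixed genome-wide $P \le 10^{-5}$
threshold, with BH available downstream if wanted.

## Loci, clusters, enrichment

Significant SNPs ($p \le \tau$, default $10^{-5}$, boundary inclusive) are
grouped per trait and chained into loci. "A region of ≤ 300 kb containing
at least two significant SNPs" is ambiguous between a cap on the total
span and a cap on consecutive gaps; the default is gap-chaining
(consecutive inter-SNP distance ≤ 300 kb, the standard clumping practice),
with a `span` mode capping total window span provided for comparison.
Chains with fewer than 2 SNPs are discarded. Cross-trait redundancy is
resolved by interval union: overlapping or bookended trait loci merge, the
merged locus carrying the SNP union and the set of contributing species.
Because "non-redundant SNPs" can be counted before or after locus
formation, the summary reports both. Coordinates are 1-based inclusive
externally (VCF/GFF convention); BED output converts to 0-based half-open.

Each locus gets a profile of its associated species' bacterial orders
(proportions summing to 1; species without an order annotation fall into
an explicit `unclassified` bucket). Loci are clustered on Bray–Curtis
distances between profiles — the same code path as the community
distances — by agglomerative clustering. The linkage is not dictated by
the methodology; we default to UPGMA (average linkage), the customary
companion to Bray–Curtis, and implement the agglomeration directly so that
ties in merge height are broken deterministically (lowest-index pair
first) — `stats::hclust` leaves tie order unspecified, which matters for
bit-reproducibility on the many tied distances proportion vectors produce.
The implementation agrees with `hclust` on tie-free instances and with a
naive $O(n^3)$ re-agglomeration oracle on all small instances. The tree is
cut at a configurable `k` (default 4, mirroring the four large clusters
such studies report; additional small clusters simply rank below), and the
summary lists each cluster's share of loci and dominant order (highest
mean member proportion; a majority-vote label would differ only for very
mixed clusters).

Locus-to-gene assignment is closed-interval overlap by ≥ 1 bp on 1-based
coordinates. Pathway enrichment is a two-sided Fisher's exact test per
(cluster, pathway) with the point-probability two-sided rule (sum of
tables at most as probable as observed, relative tolerance $10^{-7}$ — the
convention of mainstream implementations) and the sample odds ratio
$ad/bc$. Significance is raw $p < 0.05$ to match the practice the pipeline
reproduces; a BH column is provided but not used for calling. The default
background universe is all genes in the annotation; whether the universe
should instead be restricted (e.g. SNP-bearing genes) is configurable via
`universe`.

## The synthetic-data generator

The generator is first-class, tested code, and its defaults define the
conditions under which the pipeline's statistical claims are checked:

* **Genotypes.** Balding–Nichols two-level model: ancestral frequency
  $p \sim U(0.05, 0.5)$, subpopulation frequency
  $\sim \mathrm{Beta}(p(1-F)/F, (1-p)(1-F)/F)$ with $F$ = `fst` (default
  0.15; $F = 0$ degenerates to $p$ exactly), dosages binomial. Defaults:
  110 samples split 56/36/18 into three subpopulations, emulating an
  *indica*/*japonica*/unassigned diversity panel. This is the simplest
  model that produces both kinship and Q-style confounding the mixed model
  must absorb.
* **LD.** SNPs come in blocks (default 10 SNPs, 5 kb spacing, 12
  chromosomes): block members copy the anchor's genotypes with per-entry
  mutation probability 0.05. Block-copy is deliberately chosen over
  coalescent simulation — it is trivially reproducible and sufficient for
  exercising locus merging; it does not produce realistic rice LD decay.
  SNPs whose realized MAF falls below 0.05 are regenerated or dropped, so
  outputs always satisfy the MAF filter.
* **Abundances.** Latent log abundance = species baseline (SD 1) + order
  effect (SD 1) + per-(species, subpopulation) shift (SD 0.5, the
  structure confound) + planted $\beta \times$ dosage terms + Gaussian
  noise (SD = `dispersion`, default 0.5); counts are multinomial per
  sample with total $\sim$ Poisson(`depth`, default $10^5$), matching the
  relative-abundance nature of metagenome profiles rather than independent
  negative binomials. The log-normal latent trait distribution is an
  assumption, not an observed property of any panel.
* **Effect sizes.** `planted_effect_size()` converts a target variance
  share into $\beta$ using the generator's total non-genetic latent SD
  (`latent_noise_sd()`, combining dispersion and the expected
  subpopulation-shift variance), so "an effect explaining 20% of trait
  variance" means the realized trait, not just the residual noise.
* **Annotation.** Genes tile each chromosome disjointly; pathways are
  random Poisson memberships. `simulate_order_profiles()` plants known
  cluster shares for validating the locus clustering.

What passing tests on this generator do **not** show: robustness to
zero-inflation at realistic depths (defaults keep counts large),
misclassified taxonomy, fungal/viral fractions, realistic LD decay, or
non-Gaussian trait tails. They do show that the statistical machinery is
correct (oracle equivalence, calibration, recovery) under the stated
model.

## Problem sizes and numerical choices

The test suite exercises the scan at 110 samples × 5,000 SNPs × 50
species for calibration, 20 replicate simulations of 2,000 SNPs × 10
planted effects for recovery, exhaustive enumeration for the exact tests
(PERMANOVA at $n = 6$, Fisher tables with $N \le 60$, clustering up to 8
loci, 1,000 random merge instances), and a full 110 × 5,000 × 300 pipeline
run; these sizes were chosen as the smallest at which the statistical
properties of interest are identified with comfortable margins.

Numerical conventions worth knowing: kinship symmetry is enforced to
$10^{-10}$ and PSD to $-10^{-8}\lambda_{max}$; eigenvalues are clipped at
zero before weighting; REML comparisons use the analytic profile
likelihood including the $\log\det(X^\top W X)$ term; distance symmetry
and proportion sums are held to $10^{-12}$ in validation; permutation
exceedance uses a $10^{-12}$ slack so ties count as exceeding, keeping
p-values conservative. Degenerate inputs (all-zero samples, constant
traits, constant SNPs, groups of size 1, empty locus tables) raise
immediate, named errors or flagged records rather than propagating NaNs.

## Limitations

The scan re-implements the EMMAX approximation, not any particular GWAS
tool's internals, so p-values will differ in the far tail from tools using
exact per-SNP REML or different Q sources. Locus clustering shares depend
on `k` where the cluster structure is not clean. Fisher enrichment
inherits all the usual caveats of gene-set tests (gene length and locus
size are not modeled). The pipeline is single-threaded R; at the scale of
$\sim 7{,}000$ traits × $\sim 170{,}000$ SNPs a run is feasible but takes
hours, and the per-trait REML grid is then the dominant cost.
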