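# phyllogwas

Microbiome genome-wide association pipeline for phyllosphere abundance
traits.

## What this package is for

Host genetics shapes which microbes colonize plant leaves. A direct way to
find the responsible loci is to treat the abundance of every microbial
species in a panel of plant accessions as a quantitative trait and run a
genome-wide association scan per species, then ask which genomic loci,
which bacterial orders, and which host metabolic pathways the significant
associations point at. `phyllogwas` implements that chain end to end for
studies of the kind where ~110 rice accessions (two subspecies groups plus
unassigned lines) carry metagenome-derived species profiles and a
MAF-filtered SNP matrix:

1. **Abundance handling** — Bracken-style or wide count tables, taxonomy
   lineages, rank aggregation, the "mean relative abundance > 0.001%"
   species filter, and cumulative-sum scaling (CSS) normalization with
   `log2(x + 1)` trait values.
2. **Community statistics** — Shannon diversity, Bray–Curtis
   dissimilarities, PCoA, PERMANOVA (999 permutations, with an exact
   enumeration mode for small n), and per-taxon Wilcoxon or ANOVA/Tukey
   differential abundance with Benjamini–Hochberg adjustment.
3. **Mixed-model GWAS** — per-species EMMAX-style scan: VanRaden kinship
   `K`, genotype principal components `Q`, REML variance components
   estimated once per trait on the null model
   `y = X\beta + u + e`, `u ~ N(0, \sigma_g^2 K)`, then generalized least
   squares per SNP on eigen-rotated data.
4. **Locus calling** — significant SNPs (`P ≤ 1e-5`) chained into loci
   (inter-SNP gap ≤ 300 kb, ≥ 2 SNPs), merged across traits into
   non-redundant loci carrying their associated-species sets.
5. **Locus clustering** — per-locus proportions of associated species by
   bacterial order, Bray–Curtis distances between loci, deterministic
   UPGMA clustering, cluster shares and dominant orders.
6. **Pathway enrichment** — locus-to-gene overlap against a GFF3
   annotation and two-sided Fisher's exact tests per (cluster, pathway).
7. **Synthetic data** — a Balding–Nichols genotype generator with block
   LD and planted SNP→species abundance effects, so every stage runs and
   is testable without any external download.

## Worked example

```r
library(phyllogwas)

sim <- list(n_samples = 40L, subpop_sizes = c(22L, 18L), n_snps = 400L,
            n_orders = 5L, species_per_order = 6L, depth = 2e4, seed = 99L,
            planted_effects = data.frame(snp = 41L, species = 3L, beta = 1.2))
res <- run_pipeline(pipeline_config(list(seed = 7L, simulate = sim,
                                         params = list(n_perm = 99L))))
res$summary
```

```
                   metric value
1               n_samples    40
2           n_snps_tested   400
3        n_species_tested    30
4 n_significant_snp_tests     5
5                  n_loci     1
6            n_locus_snps     5
7   n_associated_species     1
8     n_enriched_pathways     0
```

The planted effect (SNP 41 on species 3) is recovered as one locus of five
significant SNPs — the planted SNP plus its LD-block neighbors — associated
with exactly one species; no pathway is enriched because the simulated
gene-to-pathway map is random. `res$scan` holds the full association table
(`beta`, `se`, `t`, `p` per SNP and species), `res$community` the
diversity/ordination results, and `res$clustering`/`res$enrichment` fill in
once at least two loci are called.

Each stage is also exposed directly (`css_normalize()`, `emmax_scan()`,
`call_trait_loci()`, `cluster_loci()`, `pathway_enrichment()`, ...), and a
thin wrapper for YAML-driven runs ships in
`inst/scripts/phyllogwas-run.R`.

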