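Package: phyllogwas
Title: Microbiome Genome-Wide Association Pipeline for Phyllosphere
    Abundance Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline from a rice genotype matrix plus
    phyllosphere species abundance profiles to community statistics,
    per-species mixed-linear-model genome-wide association scans with
    kinship and population-structure correction (EMMAX-style), merging of
    significant SNPs into non-redundant loci, clustering of loci by the
    bacterial-order composition of their associated species, and
    hypergeometric pathway enrichment. Includes a synthetic-data
    generator (Balding-Nichols population structure, block LD,
    compositional species counts with planted SNP effects) so every
    stage is exercisable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    vegan,
    vcfR,
    yaml,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
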