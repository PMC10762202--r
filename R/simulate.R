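#' Simulation configuration for the synthetic phyllosphere study
#'
#' Bundles every knob of the synthetic-data generator into a validated list.
#' The defaults emulate the structure of a diversity-panel phyllosphere
#' study: 110 accessions split into two subspecies groups (56 and 36) plus
#' 18 unassigned, biallelic SNPs with MAF >= 0.05 organized in LD blocks,
#' and compositional species counts organized into bacterial orders.
#'
#' @param n_samples Number of accessions (samples).
#' @param subpop_sizes Integer vector of subpopulation sizes; must sum to
#'   `n_samples`.
#' @param n_snps Number of SNPs to simulate (before MAF-failure drops).
#' @param fst Divergence parameter of the Balding-Nichols model, in `[0, 1)`.
#' @param maf_range Length-2 numeric, range of ancestral allele frequencies,
#'   within `(0, 0.5]`.
#' @param ld_block_size SNPs per LD block; within a block genotypes are
#'   copies of the block anchor with per-site mutation probability
#'   `mutation_rate`.
#' @param mutation_rate Per-entry probability that a copied genotype is
#'   redrawn from the block's allele frequency.
#' @param n_chrom Number of chromosomes blocks are laid out on.
#' @param snp_spacing Base pairs between adjacent SNP positions.
#' @param n_orders Number of bacterial orders.
#' @param species_per_order Species simulated per order.
#' @param planted_effects Data frame with columns `snp` (SNP index),
#'   `species` (species index) and `beta` (additive effect of one alternate
#'   allele on the latent log abundance), or `NULL` for no planted effects.
#' @param baseline_sd SD of per-species baseline log abundance.
#' @param order_sd SD of per-order log-abundance effects.
#' @param subpop_sd SD of per-(species, subpopulation) log-abundance shifts;
#'   this is the structure confounding the association scan must absorb.
#' @param depth Mean sequencing depth (reads per sample).
#' @param dispersion SD of the per-(sample, species) log-normal
#'   overdispersion noise; `0` disables it.
#' @param seed Integer seed; identical configurations give identical output.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
simulation_config <- function(n_samples = 110L,
                              subpop_sizes = c(56L, 36L, 18L),
                              n_snps = 2000L,
                              fst = 0.15,
                              maf_range = c(0.05, 0.5),
                              ld_block_size = 10L,
                              mutation_rate = 0.05,
                              n_chrom = 12L,
                              snp_spacing = 5000L,
                              n_orders = 10L,
                              species_per_order = 5L,
                              planted_effects = NULL,
                              baseline_sd = 1,
                              order_sd = 1,
                              subpop_sd = 0.5,
                              depth = 1e5,
                              dispersion = 0.5,
                              seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples), subpop_sizes = as.integer(subpop_sizes),
    n_snps = as.integer(n_snps), fst = fst, maf_range = maf_range,
    ld_block_size = as.integer(ld_block_size), mutation_rate = mutation_rate,
    n_chrom = as.integer(n_chrom), snp_spacing = as.integer(snp_spacing),
    n_orders = as.integer(n_orders),
    species_per_order = as.integer(species_per_order),
    planted_effects = planted_effects, baseline_sd = baseline_sd,
    order_sd = order_sd, subpop_sd = subpop_sd, depth = depth,
    dispersion = dispersion, seed = as.integer(seed)
  )
  if (length(cfg$subpop_sizes) < 1L || any(cfg$subpop_sizes < 1L))
    stop("subpop_sizes must be positive")
  if (sum(cfg$subpop_sizes) != cfg$n_samples)
    stop("sum(subpop_sizes) must equal n_samples")
  if (!is.numeric(fst) || fst < 0 || fst >= 1)
    stop("fst must lie in [0, 1)")
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("maf_range must lie within (0, 0.5]")
  if (cfg$depth <= 0) stop("depth must be positive")
  if (cfg$dispersion < 0) stop("dispersion must be non-negative")
  if (cfg$ld_block_size < 1L) stop("ld_block_size must be >= 1")
  if (!is.null(planted_effects)) {
    pe <- as.data.frame(planted_effects)
    if (!all(c("snp", "species", "beta") %in% names(pe)))
      stop("planted_effects needs columns snp, species, beta")
    n_species <- cfg$n_orders * cfg$species_per_order
    if (any(pe$snp < 1L) || any(pe$snp > cfg$n_snps))
      stop("planted_effects: snp index out of range")
    if (any(pe$species < 1L) || any(pe$species > n_species))
      stop("planted_effects: species index out of range")
    cfg$planted_effects <- pe
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate genotype dosages under the Balding-Nichols model
#'
#' Ancestral allele frequencies are drawn uniformly from `maf_range`; each
#' subpopulation's frequency is Beta-distributed around the ancestral value
#' with divergence `fst` (at `fst = 0` the Beta degenerates and subpopulation
#' frequencies equal the ancestral frequency exactly). Dosages are binomial
#' draws of two alleles. Linkage is induced by copying each LD block's
#' anchor genotypes with a small per-entry mutation probability. SNPs whose
#' realized sample MAF falls below 0.05 are regenerated (anchors) or, after
#' repeated failure, dropped, so the output always satisfies the MAF filter
#' applied before association scans.
#'
#' @param config A [simulation_config()] object.
#' @return A list with elements
#'   * `genotypes`: list of class `genotypes` with `dosages` (samples x SNPs
#'     integer matrix in \{0, 1, 2\}) and `map` (data frame: snp, chrom, pos,
#'     ref, alt, block),
#'   * `truth`: subpopulation labels, ancestral and per-subpopulation allele
#'     frequencies, LD-block intervals, and (once abundances are simulated)
#'     planted-effect records.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  n_pop <- length(config$subpop_sizes)
  subpop <- factor(rep(paste0("pop", seq_len(n_pop)), config$subpop_sizes))
  fst <- config$fst

  n_blocks <- ceiling(config$n_snps / config$ld_block_size)
  block_sizes <- rep(config$ld_block_size, n_blocks)
  block_sizes[n_blocks] <- config$n_snps - (n_blocks - 1L) * config$ld_block_size
  # contiguous block -> chromosome layout, whole blocks never straddle
  block_chrom <- sort(rep_len(seq_len(config$n_chrom), n_blocks))

  draw_freqs <- function() {
    p <- stats::runif(1L, config$maf_range[1], config$maf_range[2])
    if (fst == 0) {
      ps <- rep(p, n_pop)
    } else {
      a <- p * (1 - fst) / fst
      b <- (1 - p) * (1 - fst) / fst
      ps <- stats::rbeta(n_pop, a, b)
    }
    list(p = p, ps = ps)
  }
  draw_dosage <- function(ps) {
    stats::rbinom(n, 2L, rep(ps, config$subpop_sizes))
  }
  maf_of <- function(g) {
    f <- mean(g) / 2
    min(f, 1 - f)
  }

  dos <- matrix(0L, n, config$n_snps)
  p_anc <- numeric(config$n_snps)
  p_sub <- matrix(0, n_pop, config$n_snps)
  keep <- rep(TRUE, config$n_snps)
  col0 <- 0L
  for (b in seq_len(n_blocks)) {
    # regenerate the whole block's frequencies until the anchor passes MAF
    anchor <- NULL
    fr <- NULL
    for (try in 1:100) {
      fr <- draw_freqs()
      anchor <- draw_dosage(fr$ps)
      if (maf_of(anchor) >= 0.05) break
    }
    for (j in seq_len(block_sizes[b])) {
      col <- col0 + j
      if (j == 1L) {
        g <- anchor
      } else {
        g <- NULL
        for (try in 1:20) {
          g <- anchor
          mut <- stats::runif(n) < config$mutation_rate
          if (any(mut)) g[mut] <- stats::rbinom(sum(mut), 2L, rep(fr$ps, config$subpop_sizes)[mut])
          if (maf_of(g) >= 0.05) break
          g <- NULL
        }
        if (is.null(g)) {
          keep[col] <- FALSE
          next
        }
      }
      dos[, col] <- g
      p_anc[col] <- fr$p
      p_sub[, col] <- fr$ps
    }
    col0 <- col0 + block_sizes[b]
  }

  block_of <- rep(seq_len(n_blocks), block_sizes)
  # positions: SNPs evenly spaced, position index restarts per chromosome
  idx_in_chrom <- stats::ave(seq_len(config$n_snps), block_chrom[block_of],
                             FUN = seq_along)
  pos <- idx_in_chrom * config$snp_spacing
  map <- data.frame(
    snp = sprintf("snp%05d", seq_len(config$n_snps)),
    chrom = paste0("chr", block_chrom[block_of]),
    pos = as.integer(pos),
    ref = "A", alt = "G",
    block = block_of,
    stringsAsFactors = FALSE
  )
  sample_ids <- sprintf("S%03d", seq_len(n))
  dimnames(dos) <- list(sample_ids, map$snp)

  dos <- dos[, keep, drop = FALSE]
  map <- map[keep, , drop = FALSE]
  rownames(map) <- NULL
  p_anc <- p_anc[keep]
  p_sub <- p_sub[, keep, drop = FALSE]
  colnames(p_sub) <- map$snp
  names(p_anc) <- map$snp

  blocks <- do.call(rbind, lapply(split(map, map$block), function(m) {
    data.frame(block = m$block[1], chrom = m$chrom[1],
               start = min(m$pos), end = max(m$pos),
               stringsAsFactors = FALSE)
  }))
  rownames(blocks) <- NULL

  genotypes <- structure(list(dosages = dos, map = map), class = "genotypes")
  truth <- list(subpop = subpop, p_anc = p_anc, p_sub = p_sub,
                blocks = blocks, planted = config$planted_effects)
  list(genotypes = genotypes, truth = truth)
}

#' Simulate compositional species abundances with planted SNP effects
#'
#' Latent log abundance for sample i and species k is
#' `baseline_k + order_effect + subpop_shift + sum(beta * dosage) + noise`,
#' with `noise ~ Normal(0, dispersion)`. Counts for each sample are drawn
#' multinomially with total `Poisson(depth)` and probabilities proportional
#' to the latent abundances, matching the relative-abundance nature of
#' metagenome profiles. Each species belongs to exactly one bacterial order.
#'
#' @param geno Result of [simulate_genotypes()] (or its `genotypes` element
#'   together with `truth` passed via `geno`).
#' @param config The same [simulation_config()] used for the genotypes.
#' @return List with `counts` (samples x species integer matrix), `taxonomy`
#'   (data frame taxon_id, kingdom..species with a mandatory order column)
#'   and `truth` (planted-effect records with true LD-block locus intervals).
#' @export
simulate_abundances <- function(geno, config) {
  stopifnot(inherits(config, "sim_config"))
  dos <- geno$genotypes$dosages
  if (nrow(dos) != config$n_samples)
    stop("genotype/sample mismatch between geno and config")
  set.seed(config$seed + 1L)
  n <- nrow(dos)
  n_species <- config$n_orders * config$species_per_order
  order_of <- rep(seq_len(config$n_orders), each = config$species_per_order)
  order_names <- sprintf("Order_%02d", seq_len(config$n_orders))
  species_ids <- sprintf("sp%04d", seq_len(n_species))

  baseline <- stats::rnorm(n_species, 0, config$baseline_sd)
  order_eff <- stats::rnorm(config$n_orders, 0, config$order_sd)
  n_pop <- length(config$subpop_sizes)
  shift <- matrix(stats::rnorm(n_pop * n_species, 0, config$subpop_sd),
                  n_pop, n_species)
  pop_idx <- rep(seq_len(n_pop), config$subpop_sizes)

  loglam <- matrix(rep(baseline + order_eff[order_of], each = n), n, n_species)
  loglam <- loglam + shift[pop_idx, , drop = FALSE]
  pe <- config$planted_effects
  truth_rec <- NULL
  if (!is.null(pe) && nrow(pe) > 0) {
    kept_idx <- match(sprintf("snp%05d", pe$snp), geno$genotypes$map$snp)
    if (anyNA(kept_idx))
      stop("a planted SNP was dropped by the MAF filter; choose another index")
    for (r in seq_len(nrow(pe))) {
      loglam[, pe$species[r]] <- loglam[, pe$species[r]] +
        pe$beta[r] * dos[, kept_idx[r]]
    }
    blk <- geno$genotypes$map$block[kept_idx]
    bl <- geno$truth$blocks[match(blk, geno$truth$blocks$block), ]
    truth_rec <- data.frame(
      snp = geno$genotypes$map$snp[kept_idx],
      species = species_ids[pe$species],
      beta = pe$beta,
      chrom = bl$chrom, locus_start = bl$start, locus_end = bl$end,
      stringsAsFactors = FALSE
    )
  }
  if (config$dispersion > 0)
    loglam <- loglam + matrix(stats::rnorm(n * n_species, 0, config$dispersion),
                              n, n_species)

  totals <- stats::rpois(n, config$depth)
  counts <- matrix(vapply(seq_len(n), function(i) {
    pr <- exp(loglam[i, ] - max(loglam[i, ]))
    as.integer(stats::rmultinom(1L, totals[i], pr))
  }, integer(n_species)), nrow = n_species)
  counts <- t(counts)
  dimnames(counts) <- list(rownames(dos), species_ids)

  taxonomy <- data.frame(
    taxon_id = species_ids,
    kingdom = "Bacteria", phylum = "Pseudomonadota", class = "Gammaproteobacteria",
    order = order_names[order_of],
    family = paste0(order_names[order_of], "_fam"),
    genus = paste0("Genus_", order_of),
    species = paste0("Species_", seq_len(n_species)),
    stringsAsFactors = FALSE
  )
  list(counts = counts, taxonomy = taxonomy, truth = truth_rec)
}

#' Effect size for a planted association explaining a target variance share
#'
#' Returns the additive effect `beta` such that the planted term
#' `beta * dosage` explains approximately `target_r2` of the latent trait
#' variance, given the generator's residual dispersion.
#'
#' @param dosage Integer dosage vector of the planted SNP.
#' @param target_r2 Desired fraction of latent variance explained, in (0,1).
#' @param noise_sd Non-genetic latent SD; use [latent_noise_sd()] for the
#'   generator's total (dispersion plus subpopulation shifts).
#' @return A positive scalar effect size.
#' @export
planted_effect_size <- function(dosage, target_r2, noise_sd) {
  stopifnot(target_r2 > 0, target_r2 < 1)
  sg <- stats::sd(dosage)
  if (sg == 0) stop("dosage is constant")
  sqrt(target_r2 / (1 - target_r2)) * noise_sd / sg
}

#' Expected non-genetic latent SD of a simulated trait
#'
#' Combines the per-observation dispersion with the expected
#' across-sample variance contributed by the per-subpopulation shifts
#' (`subpop_sd^2 * (1 - sum(w_p^2))` with `w_p` the subpopulation sample
#' shares).
#'
#' @param config A [simulation_config()].
#' @return Scalar latent SD.
#' @export
latent_noise_sd <- function(config) {
  w <- config$subpop_sizes / config$n_samples
  sqrt(config$dispersion^2 + config$subpop_sd^2 * (1 - sum(w^2)))
}

#' Simulate a gene annotation and gene-to-pathway map
#'
#' Tiles each chromosome carrying SNPs with non-overlapping gene intervals
#' and assigns genes to pathways at random. Supports enrichment testing of
#' loci against an annotation with known structure.
#'
#' @param geno Result of [simulate_genotypes()] or a `genotypes` object.
#' @param genes_per_chrom Genes placed on each chromosome.
#' @param pathways Number of pathways.
#' @param seed Integer seed.
#' @param mean_pathways_per_gene Mean number of pathway memberships per gene
#'   (Poisson; genes may belong to zero pathways).
#' @return List with `annotation` (data frame gene_id, chrom, start, end) and
#'   `pathway_map` (data frame gene_id, pathway_id, pathway_name).
#' @export
simulate_annotation <- function(geno, genes_per_chrom = 50L, pathways = 20L,
                                seed = 1L, mean_pathways_per_gene = 1) {
  g <- if (inherits(geno, "genotypes")) geno else geno$genotypes
  stopifnot(genes_per_chrom >= 1L, pathways >= 1L)
  set.seed(seed)
  chroms <- unique(g$map$chrom)
  ann <- do.call(rbind, lapply(chroms, function(ch) {
    len <- max(g$map$pos[g$map$chrom == ch]) + 10000L
    # even tiling: gene occupies the middle 60% of its slot -> disjoint
    slot <- len / genes_per_chrom
    start <- floor((seq_len(genes_per_chrom) - 1) * slot + 0.2 * slot) + 1L
    end <- floor((seq_len(genes_per_chrom) - 1) * slot + 0.8 * slot)
    data.frame(gene_id = sprintf("gene_%s_%03d", ch, seq_len(genes_per_chrom)),
               chrom = ch, start = as.integer(start), end = as.integer(end),
               stringsAsFactors = FALSE)
  }))
  rownames(ann) <- NULL
  n_member <- stats::rpois(nrow(ann), mean_pathways_per_gene)
  pw <- do.call(rbind, lapply(seq_len(nrow(ann)), function(i) {
    if (n_member[i] == 0L) return(NULL)
    ids <- sample.int(pathways, min(n_member[i], pathways))
    data.frame(gene_id = ann$gene_id[i],
               pathway_id = sprintf("pw%03d", ids),
               pathway_name = sprintf("Pathway %03d", ids),
               stringsAsFactors = FALSE)
  }))
  if (is.null(pw))
    pw <- data.frame(gene_id = character(), pathway_id = character(),
                     pathway_name = character(), stringsAsFactors = FALSE)
  rownames(pw) <- NULL
  list(annotation = ann, pathway_map = pw)
}

#' Simulate locus order-composition profiles with planted cluster shares
#'
#' Generates per-locus proportion vectors over bacterial orders in which a
#' stated share of loci is dominated by each of the first `length(shares)`
#' orders; remaining loci are dominated by further orders, one each, so they
#' form their own small clusters. Used to exercise locus clustering against
#' a known partition.
#'
#' @param n_loci Number of loci.
#' @param shares Target shares (fractions of `n_loci`) for the planted
#'   clusters; must sum to at most 1.
#' @param n_orders Total number of orders (columns); must exceed
#'   `length(shares)`.
#' @param purity Proportion mass placed on the dominant order; the rest is
#'   spread uniformly.
#' @param noise_sd SD of proportion jitter before renormalization.
#' @param seed Integer seed.
#' @return List with `profiles` (loci x orders matrix, rows sum to 1) and
#'   `truth` (planted cluster label per locus).
#' @export
simulate_order_profiles <- function(n_loci = 100L, shares = c(0.4, 0.3, 0.15, 0.1),
                                    n_orders = 12L, purity = 0.9,
                                    noise_sd = 0.02, seed = 1L) {
  stopifnot(sum(shares) <= 1 + 1e-12, n_orders > length(shares))
  set.seed(seed)
  n_main <- round(shares * n_loci)
  n_rest <- n_loci - sum(n_main)
  dominant <- c(rep(seq_along(shares), n_main),
                rep_len(seq(length(shares) + 1L, n_orders), n_rest))
  prof <- matrix((1 - purity) / (n_orders - 1), n_loci, n_orders)
  prof[cbind(seq_len(n_loci), dominant)] <- purity
  prof <- prof + matrix(abs(stats::rnorm(n_loci * n_orders, 0, noise_sd)),
                        n_loci, n_orders)
  prof <- prof / rowSums(prof)
  dimnames(prof) <- list(sprintf("locus%03d", seq_len(n_loci)),
                         sprintf("Order_%02d", seq_len(n_orders)))
  list(profiles = prof,
       truth = factor(ifelse(dominant <= length(shares),
                             paste0("planted", dominant), "background")))
}
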