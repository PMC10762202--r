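#' Pipeline configuration
#'
#' Builds the structured configuration driving [run_pipeline()]. Either a
#' `simulate` block (a [simulation_config()] or its argument list) or a set
#' of input paths must be supplied. Can also be read from a YAML file.
#'
#' @param x A named list of settings or a path to a YAML file with the same
#'   structure. Recognized top-level keys: `seed`, `output_dir`, `simulate`
#'   (simulation settings), `inputs` (paths: `genotypes`, `abundances`,
#'   `taxonomy`, `annotation`, `pathway_map`, `groups`), and `params`
#'   (stage parameters: `min_mean_rel_abund`, `css_quantile`, `css_N`,
#'   `n_pcs`, `min_maf`, `p_threshold`, `max_gap`, `min_snps`, `linkage`,
#'   `k_clusters`, `alpha`, `n_perm`).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(x = list()) {
  if (is.character(x) && length(x) == 1L) x <- yaml::read_yaml(x)
  defaults <- list(
    seed = 1L, output_dir = NULL, simulate = NULL, inputs = list(),
    params = list()
  )
  cfg <- utils::modifyList(defaults, x)
  p_defaults <- list(min_mean_rel_abund = 1e-5, css_quantile = 0.5,
                     css_N = 1000, n_pcs = 3L, min_maf = 0.05,
                     p_threshold = 1e-5, max_gap = 300000L, min_snps = 2L,
                     linkage = "average", k_clusters = 4L, alpha = 0.05,
                     n_perm = 999L)
  cfg$params <- utils::modifyList(p_defaults, cfg$params)
  if (!is.null(cfg$simulate) && !inherits(cfg$simulate, "sim_config"))
    cfg$simulate <- do.call(simulation_config, cfg$simulate)
  if (is.null(cfg$simulate)) {
    need <- c("genotypes", "abundances", "taxonomy")
    miss <- setdiff(need, names(cfg$inputs))
    if (length(miss) > 0)
      stop("config missing input path(s): ", paste(miss, collapse = ", "))
    for (f in names(cfg$inputs)) {
      paths <- cfg$inputs[[f]]
      if (!all(file.exists(paths)))
        stop("config input '", f, "' does not exist: ", paths[1])
    }
  }
  with(cfg$params, {
    if (p_threshold <= 0 || p_threshold >= 1) stop("p_threshold out of range")
    if (css_quantile <= 0 || css_quantile >= 1) stop("css_quantile out of range")
    if (min_snps < 2) stop("min_snps must be >= 2")
  })
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the end-to-end association pipeline
#'
#' Executes: (optional) simulation of inputs, species filtering, CSS
#' normalization, community statistics (Shannon, Bray-Curtis, PCoA,
#' PERMANOVA against group labels when available), the mixed-model
#' association scan, locus calling and merging, order-profile clustering
#' of loci, and (when an annotation and pathway map are available) pathway
#' enrichment. All stage tables are written as TSV under `output_dir`
#' together with a `summary.tsv` and a key=value `pipeline.log`. Reruns
#' with an identical configuration are bit-identical.
#'
#' @param config A [pipeline_config()] (or list / YAML path coerced to one).
#' @return Invisibly, a list with all stage results and the summary.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  out_dir <- config$output_dir
  writing <- !is.null(out_dir)
  if (writing) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  log_kv <- function(...) {
    kv <- c(...)
    log_lines <<- c(log_lines,
                    paste0(names(kv), "=", unname(kv), collapse = " "))
  }
  log_kv(stage = "start", seed = config$seed)
  for (nm in names(config$params)) log_kv(stats::setNames(config$params[[nm]], nm))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  # ---- inputs ----
  truth <- NULL; groups <- NULL; annotation <- NULL; pathway_map <- NULL
  if (!is.null(config$simulate)) {
    sim_cfg <- config$simulate
    geno_sim <- stage("simulate", simulate_genotypes(sim_cfg))
    ab <- stage("simulate", simulate_abundances(geno_sim, sim_cfg))
    genotypes <- geno_sim$genotypes
    counts <- ab$counts
    taxonomy <- ab$taxonomy
    truth <- list(genotypes = geno_sim$truth, planted = ab$truth)
    groups <- geno_sim$truth$subpop
    annot <- stage("simulate",
                   simulate_annotation(geno_sim, seed = config$seed))
    annotation <- annot$annotation
    pathway_map <- annot$pathway_map
    if (writing) {
      inp <- file.path(out_dir, "inputs")
      dir.create(inp, showWarnings = FALSE)
      write_dosage_tsv(genotypes, file.path(inp, "genotypes.tsv"))
      write_vcf_genotypes(genotypes, file.path(inp, "genotypes.vcf.gz"))
      write_wide_counts(counts, file.path(inp, "abundance.tsv"))
      write_taxonomy_tsv(taxonomy, file.path(inp, "taxonomy.tsv"))
      write_gff3(annotation, file.path(inp, "annotation.gff3"))
      utils::write.table(pathway_map, file.path(inp, "pathway_map.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (!is.null(ab$truth))
        utils::write.table(ab$truth, file.path(inp, "truth.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
  } else {
    genotypes <- stage("read", {
      gp <- config$inputs$genotypes
      if (grepl("\\.vcf(\\.gz)?$", gp)) read_vcf_genotypes(gp)
      else read_dosage_tsv(gp)
    })
    counts <- stage("read", read_abundance(config$inputs$abundances,
      format = if (dir.exists(config$inputs$abundances)) "bracken_tsv" else "wide_tsv"))
    taxonomy <- stage("read", read_taxonomy(config$inputs$taxonomy))
    if (!is.null(config$inputs$annotation))
      annotation <- stage("read", read_gff_genes(config$inputs$annotation))
    if (!is.null(config$inputs$pathway_map))
      pathway_map <- stage("read", read_pathway_map(config$inputs$pathway_map))
    if (!is.null(config$inputs$groups)) {
      gdf <- utils::read.delim(config$inputs$groups, stringsAsFactors = FALSE)
      groups <- factor(gdf[[2]][match(rownames(counts), gdf[[1]])])
    }
  }
  log_kv(stage = "inputs", n_samples = nrow(counts), n_taxa = ncol(counts),
         n_snps = ncol(genotypes$dosages))

  # ---- normalization ----
  pars <- config$params
  counts_f <- stage("normalize", prevalence_filter(counts, pars$min_mean_rel_abund))
  css <- stage("normalize",
               css_normalize(counts_f, quantile = pars$css_quantile, N = pars$css_N))
  traits <- css$traits
  log_kv(stage = "normalize", n_species_kept = ncol(counts_f))

  # ---- community statistics ----
  comm <- stage("community", {
    rel <- relative_abundance(counts_f)
    shannon <- shannon_index(counts_f)
    bc <- bray_curtis(rel)
    ord <- pcoa(bc, n_axes = 2L)
    pmv <- NULL
    if (!is.null(groups) && nlevels(factor(groups)) >= 2L)
      pmv <- permanova(bc, groups, n_perm = pars$n_perm, seed = config$seed)
    list(shannon = shannon, bray_curtis = bc, pcoa = ord, permanova = pmv)
  })
  if (!is.null(comm$permanova))
    log_kv(stage = "community", permanova_F = signif(comm$permanova$F, 6),
           permanova_R2 = signif(comm$permanova$R2, 6),
           permanova_p = comm$permanova$p)

  # ---- association scan ----
  scan <- stage("gwas", {
    g <- filter_maf(genotypes, pars$min_maf)
    K <- vanraden_kinship(g)
    Keig <- kinship_eigen(K)
    Q <- genotype_pcs(g, q = pars$n_pcs)
    emmax_scan(traits, g, Keig, Q, min_maf = pars$min_maf)
  })
  log_kv(stage = "gwas", n_tests = nrow(scan),
         n_significant = sum(scan$p <= pars$p_threshold, na.rm = TRUE))

  # ---- loci ----
  sig <- stage("loci", significant_snps(scan, tau = pars$p_threshold))
  trait_loci <- stage("loci", call_trait_loci(sig, max_gap = pars$max_gap,
                                              min_snps = pars$min_snps))
  merged <- stage("loci", merge_nonredundant(trait_loci))
  log_kv(stage = "loci", n_loci = merged$summary["n_loci"],
         n_locus_snps = merged$summary["n_snps"],
         n_species = merged$summary["n_species"])

  # ---- locus clustering ----
  clustering <- NULL; profiles <- NULL
  if (nrow(merged$loci) >= 2L) {
    profiles <- stage("cluster", order_profiles(merged$loci, taxonomy))
    k_use <- min(pars$k_clusters, nrow(profiles))
    clustering <- stage("cluster", {
      dl <- locus_distance_matrix(profiles)
      cluster_loci(dl, k = k_use, linkage = pars$linkage, profiles = profiles)
    })
    log_kv(stage = "cluster", k = k_use,
           shares = paste(signif(clustering$summary$share, 4), collapse = ","))
  }

  # ---- enrichment ----
  enrichment <- NULL
  if (!is.null(annotation) && !is.null(pathway_map) && nrow(merged$loci) > 0L) {
    cl_assign <- if (!is.null(clustering)) clustering$assignment else NULL
    gene_sets <- stage("enrich", genes_in_loci(merged$loci, annotation, cl_assign))
    gene_sets <- gene_sets[vapply(gene_sets, length, integer(1)) > 0]
    if (length(gene_sets) > 0)
      enrichment <- stage("enrich",
        pathway_enrichment(gene_sets, pathway_map, annotation = annotation,
                           alpha = pars$alpha))
  }
  if (!is.null(enrichment))
    log_kv(stage = "enrich", n_tests = nrow(enrichment),
           n_significant = sum(enrichment$significant))

  # ---- summary + outputs ----
  summary <- data.frame(
    metric = c("n_samples", "n_snps_tested", "n_species_tested",
               "n_significant_snp_tests", "n_loci", "n_locus_snps",
               "n_associated_species",
               if (!is.null(clustering))
                 paste0("cluster", clustering$summary$cluster, "_share"),
               if (!is.null(enrichment)) "n_enriched_pathways"),
    value = c(nrow(counts), length(unique(scan$snp)), ncol(traits),
              sum(scan$p <= pars$p_threshold, na.rm = TRUE),
              unname(merged$summary["n_loci"]),
              unname(merged$summary["n_snps"]),
              unname(merged$summary["n_species"]),
              if (!is.null(clustering)) round(clustering$summary$share, 6),
              if (!is.null(enrichment)) sum(enrichment$significant)),
    stringsAsFactors = FALSE
  )

  if (writing) {
    utils::write.table(summary, file.path(out_dir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_matrix_tsv(traits, file.path(out_dir, "traits.tsv"))
    write_matrix_tsv(comm$bray_curtis, file.path(out_dir, "bray_curtis.tsv"))
    write_matrix_tsv(comm$pcoa$coordinates, file.path(out_dir, "pcoa.tsv"))
    utils::write.table(
      data.frame(sample_id = names(comm$shannon), shannon = comm$shannon),
      file.path(out_dir, "shannon.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(scan[, setdiff(names(scan), "degenerate")],
                       file.path(out_dir, "associations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    nm <- attr(scan, "null_models")
    utils::write.table(
      data.frame(trait = names(nm),
                 delta = vapply(nm, `[[`, numeric(1), "delta"),
                 sigma_g2 = vapply(nm, `[[`, numeric(1), "sigma_g2"),
                 sigma_e2 = vapply(nm, `[[`, numeric(1), "sigma_e2"),
                 loglik = vapply(nm, `[[`, numeric(1), "loglik")),
      file.path(out_dir, "null_models.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    if (nrow(merged$loci) > 0)
      write_loci_bed(merged$loci, file.path(out_dir, "loci.bed"),
                     file.path(out_dir, "loci.tsv"))
    if (!is.null(clustering)) {
      utils::write.table(
        data.frame(locus_id = names(clustering$assignment),
                   cluster = clustering$assignment,
                   dominant_order = clustering$summary$dominant_order[
                     clustering$assignment]),
        file.path(out_dir, "locus_clusters.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      utils::write.table(clustering$summary,
                         file.path(out_dir, "cluster_summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(enrichment))
      utils::write.table(enrichment, file.path(out_dir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    log_kv(stage = "done")
    writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  }

  invisible(list(genotypes = genotypes, counts = counts, taxonomy = taxonomy,
                 traits = traits, css_factors = css$factors, community = comm,
                 scan = scan, trait_loci = trait_loci, loci = merged$loci,
                 locus_summary = merged$summary, profiles = profiles,
                 clustering = clustering, enrichment = enrichment,
                 truth = truth, summary = summary, log = log_lines))
}
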