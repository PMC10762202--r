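#' Genes overlapping loci, collected per cluster
#'
#' A gene is included if its 1-based inclusive interval overlaps a locus
#' interval by at least one base (closed-interval overlap). Gene sets are
#' unioned over each cluster's loci.
#'
#' @param loci Merged locus data frame (needs `locus_id`, `chrom`, `start`,
#'   `end`).
#' @param annotation Gene annotation data frame (`gene_id`, `chrom`,
#'   `start`, `end`).
#' @param clusters Optional named cluster assignment (names = locus ids,
#'   as from [cluster_loci()]); if `NULL` every locus forms its own set.
#' @return Named list of character vectors of gene ids.
#' @export
genes_in_loci <- function(loci, annotation, clusters = NULL) {
  per_locus <- lapply(seq_len(nrow(loci)), function(i) {
    hit <- annotation$chrom == loci$chrom[i] &
      annotation$start <= loci$end[i] & annotation$end >= loci$start[i]
    annotation$gene_id[hit]
  })
  names(per_locus) <- loci$locus_id
  if (is.null(clusters))
    return(lapply(per_locus, function(g) sort(unique(g))))
  cl <- clusters[loci$locus_id]
  out <- lapply(split(per_locus, cl), function(sets) sort(unique(unlist(sets))))
  names(out) <- paste0("cluster", names(out))
  out
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' For the table `[[a, b], [c, d]]` with fixed margins, the two-sided
#' p-value sums the hypergeometric probabilities of every table whose
#' probability is at most that of the observed one (point-probability
#' rule, relative tolerance 1e-7 — the convention of mainstream exact-test
#' implementations). The odds ratio is the sample `ad/bc` (with
#' `Inf`/`NaN` handling for zero cells).
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return List with `odds_ratio` and `p`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cells must be non-negative integers")
  m <- a + b          # row 1
  n2 <- c + d         # row 2
  k <- a + c          # column 1
  if (m == 0 || n2 == 0 || k == 0 || b + d == 0) {
    p <- 1
  } else {
    support <- max(0L, k - n2):min(k, m)
    probs <- stats::dhyper(support, m, n2, k)
    p_obs <- stats::dhyper(a, m, n2, k)
    p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  }
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c)
  list(odds_ratio = or, p = p)
}

#' Pathway enrichment per locus cluster
#'
#' One two-sided Fisher's exact test per (cluster, pathway): `a` cluster
#' genes in the pathway, `K` universe genes in the pathway, `n` cluster
#' genes in the universe, `N` universe size. Significance is called at the
#' raw `p < alpha` (default 0.05); a Benjamini-Hochberg column is provided
#' alongside.
#'
#' @param gene_sets Named list of cluster gene-id vectors
#'   (from [genes_in_loci()]).
#' @param pathway_map Data frame `gene_id`, `pathway_id`, `pathway_name`.
#' @param universe Background gene universe; defaults to all genes in
#'   `annotation` if given, else all genes in the pathway map.
#' @param annotation Optional gene annotation supplying the default
#'   universe.
#' @param alpha Raw significance threshold.
#' @return Data frame with `cluster`, `pathway_id`, `pathway_name`, `a`,
#'   `K`, `n`, `N`, `odds_ratio`, `p`, `p_bh`, `significant`.
#' @export
pathway_enrichment <- function(gene_sets, pathway_map, universe = NULL,
                               annotation = NULL, alpha = 0.05) {
  if (is.null(universe))
    universe <- if (!is.null(annotation)) unique(annotation$gene_id)
                else unique(pathway_map$gene_id)
  if (length(universe) == 0L) stop("empty gene universe")
  N <- length(universe)
  pw_split <- split(pathway_map$gene_id, pathway_map$pathway_id)
  pw_split <- lapply(pw_split, function(g) intersect(unique(g), universe))
  pw_names <- vapply(split(pathway_map$pathway_name, pathway_map$pathway_id),
                     `[`, character(1), 1L)
  rows <- list()
  for (cl in names(gene_sets)) {
    genes <- unique(gene_sets[[cl]])
    outside <- setdiff(genes, universe)
    if (length(outside) > 0) {
      warning(length(outside), " cluster genes outside the universe dropped")
      genes <- intersect(genes, universe)
    }
    n_cl <- length(genes)
    for (pw in names(pw_split)) {
      K <- length(pw_split[[pw]])
      a <- length(intersect(genes, pw_split[[pw]]))
      ft <- fisher_exact_2x2(a, n_cl - a, K - a, N - K - n_cl + a)
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, pathway_id = pw, pathway_name = unname(pw_names[pw]),
        a = a, K = K, n = n_cl, N = N, odds_ratio = ft$odds_ratio, p = ft$p,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out$p_bh <- stats::ave(out$p, out$cluster,
                         FUN = function(p) stats::p.adjust(p, "BH"))
  out$significant <- out$p < alpha
  rownames(out) <- NULL
  out
}
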