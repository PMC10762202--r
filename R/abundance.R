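#' Read a taxonomic abundance table
#'
#' Supports two layouts: a wide TSV with one row per taxon (first column
#' `taxon_id`, remaining columns one sample each) or a set of per-sample
#' Bracken species reports. For Bracken reports the estimated read count
#' (`new_est_reads`) is used and the `fraction_total_reads` column ignored;
#' taxa absent from a sample's report get a zero count (union over samples).
#'
#' @param path For `wide_tsv`, a single file; for `bracken_tsv`, a character
#'   vector of report files or a directory containing `*.bracken.tsv` files.
#' @param format `"wide_tsv"` or `"bracken_tsv"`.
#' @return Samples x taxa integer count matrix.
#' @export
read_abundance <- function(path, format = c("wide_tsv", "bracken_tsv")) {
  format <- match.arg(format)
  if (format == "wide_tsv") {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (names(df)[1] != "taxon_id") stop("wide TSV must start with taxon_id")
    if (anyDuplicated(df$taxon_id)) stop("duplicate taxon ids in ", path)
    m <- as.matrix(df[, -1, drop = FALSE])
    if (any(is.na(m)) || any(m < 0)) stop("negative or missing counts in ", path)
    if (any(m != round(m))) stop("non-integer counts in ", path)
    counts <- t(m)
    storage.mode(counts) <- "integer"
    colnames(counts) <- df$taxon_id
    return(counts)
  }
  files <- path
  if (length(files) == 1L && dir.exists(files))
    files <- list.files(files, pattern = "\\.bracken\\.tsv$", full.names = TRUE)
  if (length(files) == 0L) stop("no bracken report files found")
  per_sample <- lapply(files, function(f) {
    df <- utils::read.delim(f, stringsAsFactors = FALSE)
    need <- c("name", "new_est_reads")
    if (!all(need %in% names(df))) stop("malformed bracken report: ", f)
    if (anyDuplicated(df$name)) stop("duplicate taxon ids in ", f)
    if (any(df$new_est_reads < 0)) stop("negative counts in ", f)
    stats::setNames(as.integer(df$new_est_reads), df$name)
  })
  samples <- sub("\\.bracken\\.tsv$", "", basename(files))
  taxa <- sort(unique(unlist(lapply(per_sample, names))))
  counts <- matrix(0L, length(samples), length(taxa),
                   dimnames = list(samples, taxa))
  for (i in seq_along(per_sample))
    counts[i, names(per_sample[[i]])] <- per_sample[[i]]
  counts
}

#' Aggregate a count table at a taxonomic rank
#'
#' Counts of taxa sharing the same label at `rank` are summed; taxa whose
#' lineage lacks the rank are pooled into an `unclassified_<rank>` bucket.
#' Output columns are ordered by descending total abundance.
#'
#' @param counts Samples x taxa count matrix.
#' @param taxonomy Lineage table with `taxon_id` and rank columns.
#' @param rank Rank column name, e.g. `"order"`.
#' @return Samples x groups count matrix.
#' @export
aggregate_rank <- function(counts, taxonomy, rank = "order") {
  if (!rank %in% names(taxonomy)) stop("rank '", rank, "' not in taxonomy")
  lab <- taxonomy[[rank]][match(colnames(counts), taxonomy$taxon_id)]
  missing <- is.na(lab) | lab == ""
  if (any(missing)) {
    warning(sum(missing), " taxa without ", rank,
            " annotation pooled into unclassified_", rank)
    lab[missing] <- paste0("unclassified_", rank)
  }
  groups <- unique(lab)
  agg <- vapply(groups, function(g)
    rowSums(counts[, lab == g, drop = FALSE]), numeric(nrow(counts)))
  if (nrow(counts) == 1L) agg <- matrix(agg, 1L, dimnames = list(rownames(counts), groups))
  agg <- agg[, order(colSums(agg), decreasing = TRUE), drop = FALSE]
  storage.mode(agg) <- storage.mode(counts)
  agg
}

#' Convert counts to relative abundances
#'
#' @param counts Samples x taxa non-negative matrix.
#' @return Matrix of the same shape with rows summing to 1.
#' @export
relative_abundance <- function(counts) {
  tot <- rowSums(counts)
  bad <- tot <= 0
  if (any(bad))
    stop("all-zero sample(s): ", paste(rownames(counts)[bad], collapse = ", "))
  counts / tot
}

#' Filter taxa by mean relative abundance
#'
#' Keeps taxa whose average relative abundance across samples strictly
#' exceeds the threshold. The default 1e-5 corresponds to the common
#' "average relative abundance > 0.001%" species filter.
#'
#' @param counts Samples x taxa count matrix.
#' @param min_mean_rel_abund Strict lower threshold on the mean relative
#'   abundance.
#' @return The filtered count matrix.
#' @export
prevalence_filter <- function(counts, min_mean_rel_abund = 1e-5) {
  keep <- colMeans(relative_abundance(counts)) > min_mean_rel_abund
  counts[, keep, drop = FALSE]
}

#' Cumulative-sum scaling normalization
#'
#' For each sample j, let `q_j` be the `quantile`-th quantile of its nonzero
#' counts (linear-interpolation convention, `type = 7`); the scaling factor
#' `s_j` is the sum of counts at or below `q_j`. Normalized values are
#' `count / s_j * N`, and trait values for association scans are
#' `log2(normalized + 1)`.
#'
#' Quantiles are taken over nonzero counts only, so structural zeros do not
#' drag the scaling factor down.
#'
#' @param counts Samples x taxa count matrix; every sample needs at least
#'   one nonzero count.
#' @param quantile Quantile `l` in (0, 1); default median.
#' @param N Normalization constant.
#' @param log2_transform If `TRUE` (default) return `log2(x + 1)` trait
#'   values, else the CSS-scaled values themselves.
#' @return List with `traits` (samples x taxa numeric matrix) and `factors`
#'   (data frame: sample_id, quantile_value, scaling_factor).
#' @export
css_normalize <- function(counts, quantile = 0.5, N = 1000,
                          log2_transform = TRUE) {
  if (quantile <= 0 || quantile >= 1) stop("quantile must lie in (0, 1)")
  tot <- rowSums(counts)
  if (any(tot <= 0))
    stop("all-zero sample(s): ",
         paste(rownames(counts)[tot <= 0], collapse = ", "))
  qs <- numeric(nrow(counts))
  s <- numeric(nrow(counts))
  for (j in seq_len(nrow(counts))) {
    x <- counts[j, ]
    qs[j] <- stats::quantile(x[x > 0], probs = quantile, type = 7, names = FALSE)
    s[j] <- sum(x[x <= qs[j]])
  }
  norm <- counts / s * N
  traits <- if (log2_transform) log2(norm + 1) else norm
  list(traits = traits,
       factors = data.frame(sample_id = rownames(counts),
                            quantile_value = qs, scaling_factor = s,
                            stringsAsFactors = FALSE))
}
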