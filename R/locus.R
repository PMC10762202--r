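#' Significant SNPs per trait
#'
#' Filters association records at `p <= tau` (inclusive threshold) and
#' returns them grouped by trait, sorted by chromosome then position.
#'
#' @param assoc Association data frame from [emmax_scan()].
#' @param tau Significance threshold (default the genome-wide 1e-5).
#' @return Named list (one element per trait with hits) of data frames with
#'   `snp`, `chrom`, `pos`, `p`.
#' @export
significant_snps <- function(assoc, tau = 1e-5) {
  if (tau <= 0 || tau >= 1) stop("tau must lie in (0, 1)")
  sig <- assoc[!is.na(assoc$p) & assoc$p <= tau,
               c("trait", "snp", "chrom", "pos", "p")]
  if (nrow(sig) == 0L) return(list())
  sig <- sig[order(sig$trait, sig$chrom, sig$pos), ]
  out <- split(sig[, c("snp", "chrom", "pos", "p")], sig$trait)
  lapply(out, function(df) { rownames(df) <- NULL; df })
}

#' Call per-trait loci from significant SNPs
#'
#' Default `gap` mode chains consecutive significant SNPs on the same
#' chromosome whose inter-SNP distance is at most `max_gap` (300 kb by
#' default); `span` mode instead grows greedy left-to-right windows whose
#' total span is at most `max_gap`. Chains with fewer than `min_snps`
#' members are discarded. The locus interval is the 1-based inclusive span
#' of its member SNPs.
#'
#' @param snps Per-trait significant-SNP list from [significant_snps()],
#'   or a single data frame with `snp`, `chrom`, `pos`.
#' @param max_gap Maximum chaining distance (gap mode) or window span
#'   (span mode), in bp; boundary inclusive.
#' @param min_snps Minimum SNPs per locus (>= 2).
#' @param merge_mode `"gap"` or `"span"`.
#' @return Data frame with `trait`, `chrom`, `start`, `end` and list-column
#'   `snps` of member SNP ids.
#' @export
call_trait_loci <- function(snps, max_gap = 300000L, min_snps = 2L,
                            merge_mode = c("gap", "span")) {
  merge_mode <- match.arg(merge_mode)
  if (min_snps < 2L) stop("min_snps must be >= 2")
  if (max_gap <= 0) stop("max_gap must be positive")
  if (is.data.frame(snps)) snps <- list(trait = snps)
  res <- list()
  for (tr in names(snps)) {
    df <- snps[[tr]]
    for (ch in unique(df$chrom)) {
      sub <- df[df$chrom == ch, ]
      if (is.unsorted(sub$pos)) stop("positions must be sorted within chromosome")
      pos <- sub$pos
      if (merge_mode == "gap") {
        brk <- c(0, cumsum(diff(pos) > max_gap))
      } else {
        brk <- integer(length(pos))
        cur <- 0L
        anchor <- pos[1]
        for (i in seq_along(pos)) {
          if (pos[i] - anchor > max_gap) {
            cur <- cur + 1L
            anchor <- pos[i]
          }
          brk[i] <- cur
        }
      }
      for (grp in split(seq_along(pos), brk)) {
        if (length(grp) < min_snps) next
        res[[length(res) + 1L]] <- data.frame(
          trait = tr, chrom = ch, start = min(pos[grp]), end = max(pos[grp]),
          snps = I(list(sub$snp[grp])), stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(res) == 0L)
    return(data.frame(trait = character(), chrom = character(),
                      start = integer(), end = integer(),
                      snps = I(list()), stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out <- out[order(out$trait, out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

#' Merge per-trait loci into non-redundant loci
#'
#' Overlapping or bookended (directly adjacent) trait loci on the same
#' chromosome are merged by interval union. A merged locus carries the
#' union of member SNP ids and the set of associated species (every trait
#' that contributed a locus to the merge). The summary reports the numbers
#' of distinct significant SNPs counted both before locus formation (all
#' SNPs in any trait locus) and after (SNPs in merged loci), the number of
#' loci, and the number of associated species.
#'
#' @param trait_loci Data frame from [call_trait_loci()].
#' @return List with `loci` (data frame: locus_id, chrom, start, end,
#'   list-columns `snps` and `species`) and `summary` (named numeric).
#' @export
merge_nonredundant <- function(trait_loci) {
  if (nrow(trait_loci) == 0L) {
    loci <- data.frame(locus_id = character(), chrom = character(),
                       start = integer(), end = integer(),
                       snps = I(list()), species = I(list()),
                       stringsAsFactors = FALSE)
    return(list(loci = loci,
                summary = c(n_snps_pre_merge = 0, n_snps = 0, n_loci = 0,
                            n_species = 0)))
  }
  pieces <- list()
  for (ch in unique(trait_loci$chrom)) {
    sub <- trait_loci[trait_loci$chrom == ch, ]
    sub <- sub[order(sub$start, sub$end), ]
    cur_start <- sub$start[1]; cur_end <- sub$end[1]
    cur_snps <- sub$snps[[1]]; cur_sp <- sub$trait[1]
    flush <- function() {
      pieces[[length(pieces) + 1L]] <<- data.frame(
        chrom = ch, start = cur_start, end = cur_end,
        snps = I(list(sort(unique(unlist(cur_snps))))),
        species = I(list(sort(unique(unlist(cur_sp))))),
        stringsAsFactors = FALSE)
    }
    if (nrow(sub) > 1L) for (i in 2:nrow(sub)) {
      if (sub$start[i] <= cur_end + 1L) {  # overlap or bookended
        cur_end <- max(cur_end, sub$end[i])
        cur_snps <- c(cur_snps, sub$snps[[i]])
        cur_sp <- c(cur_sp, sub$trait[i])
      } else {
        flush()
        cur_start <- sub$start[i]; cur_end <- sub$end[i]
        cur_snps <- sub$snps[[i]]; cur_sp <- sub$trait[i]
      }
    }
    flush()
  }
  loci <- do.call(rbind, pieces)
  ord <- order(loci$chrom, loci$start)
  loci <- loci[ord, ]
  loci$locus_id <- sprintf("locus%03d", seq_len(nrow(loci)))
  loci <- loci[, c("locus_id", "chrom", "start", "end", "snps", "species")]
  rownames(loci) <- NULL
  summary <- c(
    n_snps_pre_merge = length(unique(unlist(trait_loci$snps))),
    n_snps = length(unique(unlist(loci$snps))),
    n_loci = nrow(loci),
    n_species = length(unique(unlist(loci$species)))
  )
  list(loci = loci, summary = summary)
}
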