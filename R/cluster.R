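#' Order-level composition profiles of loci
#'
#' For each locus, the proportion of its associated species annotated to
#' each bacterial order. Species without an order annotation fall into an
#' `"unclassified"` bucket (with a warning).
#'
#' @param loci Merged locus data frame from [merge_nonredundant()] (needs
#'   `locus_id` and list-column `species`).
#' @param taxonomy Lineage table with `taxon_id` and `order` columns.
#' @return Loci x orders matrix of proportions; rows sum to 1.
#' @export
order_profiles <- function(loci, taxonomy) {
  lookup <- stats::setNames(taxonomy$order, taxonomy$taxon_id)
  all_sp <- unlist(loci$species)
  labs <- lookup[all_sp]
  if (anyNA(labs) || any(labs == "")) {
    warning("species without order annotation assigned to 'unclassified'")
  }
  get_orders <- function(sp) {
    o <- lookup[sp]
    o[is.na(o) | o == ""] <- "unclassified"
    o
  }
  orders <- sort(unique(get_orders(all_sp)))
  prof <- t(vapply(seq_len(nrow(loci)), function(i) {
    o <- get_orders(loci$species[[i]])
    tab <- table(factor(o, levels = orders))
    as.numeric(tab) / length(o)
  }, numeric(length(orders))))
  dimnames(prof) <- list(loci$locus_id, orders)
  prof
}

#' Bray-Curtis distances between locus order profiles
#'
#' Identical computation to [bray_curtis()] on the community side; the two
#' share one code path.
#'
#' @param profiles Loci x orders proportion matrix.
#' @return Symmetric loci x loci distance matrix.
#' @export
locus_distance_matrix <- function(profiles) {
  if (nrow(profiles) < 2L) stop("need at least two locus profiles")
  bray_curtis(profiles)
}

#' Agglomerative hierarchical clustering of loci
#'
#' Plain agglomerative clustering with `average` (UPGMA), `single` or
#' `complete` linkage and a deterministic tie-break: among pairs at equal
#' merge height, the pair with the lowest indices is merged first. The tree
#' is cut into `k` clusters. The summary reports each cluster's share of
#' all loci and its dominant order (highest mean member proportion),
#' ordered by decreasing size.
#'
#' @param d Loci x loci distance matrix.
#' @param k Number of clusters.
#' @param linkage `"average"`, `"single"` or `"complete"`.
#' @param profiles Optional loci x orders proportion matrix used to label
#'   each cluster's dominant order.
#' @return List of class `locus_clustering` with `assignment` (named
#'   integer cluster per locus, labeled 1..k by decreasing size), `merges`
#'   and `heights` (agglomeration history), `k`, `linkage` and `summary`
#'   (data frame: cluster, n_loci, share, dominant_order).
#' @export
cluster_loci <- function(d, k, linkage = c("average", "single", "complete"),
                         profiles = NULL) {
  linkage <- match.arg(linkage)
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (k < 1L || k > n) stop("k must lie in [1, number of loci]")
  ids <- rownames(dm)
  if (is.null(ids)) ids <- paste0("locus", seq_len(n))

  # active clusters: list of member index vectors; merge lowest (h, i, j)
  members <- as.list(seq_len(n))
  active <- rep(TRUE, n + max(0L, n - 1L))
  cd <- matrix(Inf, length(active), length(active))
  cd[seq_len(n), seq_len(n)] <- dm
  diag(cd) <- Inf
  merges <- matrix(0L, 0L, 2L)
  heights <- numeric(0)
  assignment_at <- function(n_clusters) {
    # replay merges until n_clusters remain
    grp <- seq_len(n)
    cl <- as.list(seq_len(n))
    steps <- n - n_clusters
    for (s in seq_len(steps)) {
      a <- merges[s, 1]; b <- merges[s, 2]
      cl[[n + s]] <- c(cl[[a]], cl[[b]])
      cl[[a]] <- integer(0); cl[[b]] <- integer(0)
    }
    out <- integer(n)
    live <- which(lengths(cl) > 0)
    for (ci in seq_along(live)) out[cl[[live[ci]]]] <- ci
    out
  }
  if (n > 1L) {
    alive <- seq_len(n)
    for (s in seq_len(n - 1L)) {
      # lowest height; ties broken by the lowest (i, j) pair
      best_h <- Inf; a <- NA_integer_; b <- NA_integer_
      for (ii in seq_len(length(alive) - 1L)) {
        cand <- alive[(ii + 1L):length(alive)]
        row <- cd[alive[ii], cand]
        m <- min(row)
        if (m < best_h - 1e-15) {
          best_h <- m; a <- alive[ii]; b <- cand[which.min(row)]
        }
      }
      new <- n + s
      merges <- rbind(merges, c(a, b))
      heights <- c(heights, best_h)
      members[[new]] <- c(members[[a]], members[[b]])
      na <- length(members[[a]]); nb <- length(members[[b]])
      rest <- setdiff(alive, c(a, b))
      for (r in rest) {
        cd[new, r] <- cd[r, new] <- switch(linkage,
          average = (na * cd[a, r] + nb * cd[b, r]) / (na + nb),
          single = min(cd[a, r], cd[b, r]),
          complete = max(cd[a, r], cd[b, r]))
      }
      alive <- c(rest, new)
    }
  }
  raw <- assignment_at(k)
  # relabel clusters 1..k by decreasing size (ties: first occurrence)
  sizes <- table(raw)
  ord <- order(-as.numeric(sizes), as.integer(names(sizes)))
  relab <- stats::setNames(seq_along(ord), names(sizes)[ord])
  assignment <- stats::setNames(relab[as.character(raw)], ids)

  dominant <- rep(NA_character_, k)
  if (!is.null(profiles)) {
    for (c0 in seq_len(k)) {
      mem <- which(assignment == c0)
      mp <- colMeans(profiles[mem, , drop = FALSE])
      dominant[c0] <- colnames(profiles)[which.max(mp)]
    }
  }
  summary <- data.frame(
    cluster = seq_len(k),
    n_loci = as.integer(table(factor(assignment, levels = seq_len(k)))),
    stringsAsFactors = FALSE
  )
  summary$share <- summary$n_loci / n
  summary$dominant_order <- dominant
  structure(list(assignment = assignment, merges = merges, heights = heights,
                 k = k, linkage = linkage, summary = summary),
            class = "locus_clustering")
}
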