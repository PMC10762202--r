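#' Shannon diversity index per sample
#'
#' `H = -sum(p_i * log(p_i))` over nonzero proportions, natural logarithm.
#'
#' @param counts Samples x taxa non-negative matrix (or a single count
#'   vector).
#' @return Named numeric vector of Shannon indices.
#' @export
shannon_index <- function(counts) {
  if (is.null(dim(counts))) counts <- matrix(counts, 1L)
  if (any(rowSums(counts) <= 0)) stop("all-zero sample")
  vegan::diversity(counts, index = "shannon")
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = sum(|x - y|) / sum(x + y)` on non-negative profiles. Returned
#' as a full symmetric matrix with zero diagonal.
#'
#' @param x Samples x taxa non-negative matrix.
#' @return Symmetric samples x samples matrix in `[0, 1]`.
#' @export
bray_curtis <- function(x) {
  if (any(x < 0)) stop("Bray-Curtis needs non-negative values")
  zero <- rowSums(x) == 0
  if (sum(zero) >= 2L)
    stop("Bray-Curtis undefined for pairs of all-zero samples: ",
         paste(rownames(x)[zero], collapse = ", "))
  d <- as.matrix(vegan::vegdist(x, method = "bray"))
  diag(d) <- 0
  d
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centers `-D^2/2` and eigendecomposes it (via [stats::cmdscale()]).
#' Coordinates are eigenvectors scaled by the square root of their (positive)
#' eigenvalues. Negative eigenvalues are reported but excluded from the
#' explained-variance denominator. Axis signs are fixed so each axis's
#' largest-magnitude coordinate is positive.
#'
#' @param d Distance matrix (full symmetric matrix or `dist`).
#' @param n_axes Number of axes requested; silently truncated (with a
#'   warning) to the number of positive eigenvalues.
#' @return List with `coordinates` (samples x axes), `eigenvalues` (all,
#'   descending) and `proportion_explained` (per returned axis, over
#'   positive eigenvalues only).
#' @export
pcoa <- function(d, n_axes = 2L) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  fit <- suppressWarnings(stats::cmdscale(dm, k = n - 1L, eig = TRUE))
  eig <- fit$eig
  pos <- sum(eig > sqrt(.Machine$double.eps) * max(abs(eig)))
  if (n_axes > pos) {
    warning("only ", pos, " positive eigenvalues; returning ", pos, " axes")
    n_axes <- pos
  }
  coords <- fit$points[, seq_len(n_axes), drop = FALSE]
  for (k in seq_len(ncol(coords))) {
    j <- which.max(abs(coords[, k]))
    if (coords[j, k] < 0) coords[, k] <- -coords[, k]
  }
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  list(coordinates = coords,
       eigenvalues = sort(eig, decreasing = TRUE),
       proportion_explained = eig[seq_len(n_axes)] / sum(eig[eig > 0]))
}

#' PERMANOVA on a distance matrix
#'
#' Distance-based pseudo-F (Anderson's formulation): with total sum of
#' squares `SST = sum(d_ij^2)/n` over all pairs and within-group
#' `SSW = sum_g sum(d_ij^2)/n_g` over within-group pairs,
#' `F = (SSB/(a-1)) / (SSW/(n-a))` where `SSB = SST - SSW` and `a` is the
#' number of groups. The p-value is `(1 + #{permuted F >= observed}) /
#' (1 + n_perm)` under random relabelings, or the exact proportion over all
#' `n!` relabelings when `exact = TRUE` (feasible for small n).
#'
#' @param d Distance matrix (full symmetric matrix or `dist`).
#' @param groups Factor (or coercible) of group labels, one per sample.
#' @param n_perm Number of random permutations (ignored when `exact`).
#' @param seed Integer seed for the permutation stream.
#' @param exact If `TRUE`, enumerate all relabelings (requires `n <= 9`).
#' @return List with `F`, `R2`, `p`, `n_perm`, `seed`, `exact`.
#' @export
permanova <- function(d, groups, n_perm = 999L, seed = 1L, exact = FALSE) {
  dm <- as.matrix(d)
  groups <- factor(groups)
  n <- nrow(dm)
  if (length(groups) != n) stop("groups length must match distance matrix")
  tab <- table(groups)
  if (length(tab) < 2L) stop("need at least two groups")
  if (any(tab < 2L)) stop("every group needs at least two samples")
  d2 <- dm^2
  sst <- sum(d2[upper.tri(d2)]) / n
  a <- length(tab)
  fstat <- function(g) {
    ssw <- 0
    for (lev in levels(groups)) {
      idx <- which(g == lev)
      ssw <- ssw + sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
    }
    ssb <- sst - ssw
    (ssb / (a - 1)) / (ssw / (n - a))
  }
  f_obs <- fstat(groups)
  ssw <- 0
  for (lev in levels(groups)) {
    idx <- which(groups == lev)
    ssw <- ssw + sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
  }
  r2 <- (sst - ssw) / sst

  if (exact) {
    if (n > 9L) stop("exact enumeration limited to n <= 9")
    perms <- permutations_of(n)
    f_perm <- apply(perms, 1L, function(ix) fstat(groups[ix]))
    p <- mean(f_perm >= f_obs - 1e-12)
    n_used <- nrow(perms)
  } else {
    set.seed(seed)
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      if (fstat(groups[sample.int(n)]) >= f_obs - 1e-12) exceed <- exceed + 1L
    }
    p <- (1 + exceed) / (1 + n_perm)
    n_used <- n_perm
  }
  list(F = f_obs, R2 = r2, p = p, n_perm = n_used, seed = seed, exact = exact)
}

# all n! permutations of 1..n as a matrix (rows)
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- nrow(sub)
    out[r + seq_len(rows), ] <- cbind(k, matrix(c(seq_len(n)[-k])[sub], rows))
    r <- r + rows
  }
  out
}

#' Per-taxon differential abundance between groups
#'
#' `wilcoxon`: two-sided rank-sum test (normal approximation with tie
#' correction; exact enumeration when the combined group size is at most 10
#' and there are no ties). `anova_tukey`: one-way ANOVA F test with Tukey
#' HSD pairwise comparisons (studentized-range distribution); the reported
#' raw p is the ANOVA p and the pairwise Tukey p-values are appended as
#' columns. Benjamini-Hochberg adjustment is applied across taxa.
#'
#' @param values Samples x taxa numeric matrix (counts, relative abundances
#'   or transformed values).
#' @param groups Factor of group labels per sample.
#' @param method `"wilcoxon"` (two groups) or `"anova_tukey"`.
#' @return Data frame with per-taxon group means, statistic, raw `p`,
#'   BH-adjusted `p_adj` and the test name (plus `tukey_*` columns for
#'   `anova_tukey`).
#' @export
differential_abundance <- function(values, groups,
                                   method = c("wilcoxon", "anova_tukey")) {
  method <- match.arg(method)
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least two groups")
  if (method == "wilcoxon" && nlevels(groups) != 2L)
    stop("wilcoxon requires exactly two groups")
  if (method == "anova_tukey" && any(table(groups) < 2L))
    stop("anova_tukey needs >= 2 samples per group")
  taxa <- colnames(values)
  means <- t(vapply(seq_len(ncol(values)), function(j)
    tapply(values[, j], groups, mean), numeric(nlevels(groups))))
  colnames(means) <- paste0("mean_", levels(groups))

  if (method == "wilcoxon") {
    g1 <- groups == levels(groups)[1]
    res <- lapply(seq_len(ncol(values)), function(j) {
      x <- values[g1, j]; y <- values[!g1, j]
      use_exact <- (length(x) + length(y)) <= 10 &&
        !anyDuplicated(c(x, y))
      w <- suppressWarnings(stats::wilcox.test(x, y, exact = use_exact,
                                               correct = FALSE))
      c(stat = unname(w$statistic), p = w$p.value)
    })
    stat <- vapply(res, `[[`, numeric(1), "stat")
    p <- vapply(res, `[[`, numeric(1), "p")
    out <- data.frame(taxon = taxa, means, stat = stat, p = p,
                      p_adj = stats::p.adjust(p, "BH"),
                      test = "wilcoxon", stringsAsFactors = FALSE,
                      check.names = FALSE)
  } else {
    pair_names <- NULL
    res <- lapply(seq_len(ncol(values)), function(j) {
      fit <- stats::aov(values[, j] ~ groups)
      an <- summary(fit)[[1]]
      tk <- stats::TukeyHSD(fit)$groups
      list(stat = an[1, "F value"], p = an[1, "Pr(>F)"],
           tukey = stats::setNames(tk[, "p adj"], rownames(tk)))
    })
    pair_names <- names(res[[1]]$tukey)
    tukey <- t(vapply(res, function(r) r$tukey, numeric(length(pair_names))))
    colnames(tukey) <- paste0("tukey_", gsub("-", "_vs_", pair_names))
    p <- vapply(res, `[[`, numeric(1), "p")
    out <- data.frame(taxon = taxa, means,
                      stat = vapply(res, `[[`, numeric(1), "stat"),
                      p = p, p_adj = stats::p.adjust(p, "BH"),
                      test = "anova_tukey", tukey,
                      stringsAsFactors = FALSE, check.names = FALSE)
  }
  rownames(out) <- NULL
  out
}
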