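# Independent oracle implementations used across the suite. These are kept
# deliberately naive (direct formulas, dense algebra, exhaustive search) and
# separate from the package's code paths.

# Weir-Cockerham FST estimator across SNPs (multi-population, diploid,
# assuming HWE so heterozygosity enters through allele frequencies).
wc_fst <- function(dosages, subpop) {
  subpop <- factor(subpop)
  r <- nlevels(subpop)
  n_i <- as.numeric(table(subpop))
  nbar <- mean(n_i)
  nc <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
  num <- den <- 0
  for (j in seq_len(ncol(dosages))) {
    p_i <- tapply(dosages[, j], subpop, mean) / 2
    pbar <- sum(n_i * p_i) / sum(n_i)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * 2 * p_i * (1 - p_i)) / sum(n_i)
    a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

# columnwise mean imputation (kept separate from the package's version)
impute_mean_oracle <- function(dos) {
  for (j in seq_len(ncol(dos))) {
    na <- is.na(dos[, j])
    if (any(na)) dos[na, j] <- mean(dos[!na, j])
  }
  dos
}

# dense-matrix GLS association oracle: direct inversion of sigma_g2*K + sigma_e2*I
gls_oracle <- function(y, X, G, K, delta) {
  n <- length(y)
  V <- K + delta * diag(n)
  Vi <- solve(V)
  out <- matrix(NA_real_, ncol(G), 3,
                dimnames = list(colnames(G), c("beta", "se", "p")))
  for (j in seq_len(ncol(G))) {
    Z <- cbind(X, g = G[, j])
    A <- solve(t(Z) %*% Vi %*% Z)
    bhat <- A %*% t(Z) %*% Vi %*% y
    r <- y - Z %*% bhat
    df <- n - ncol(Z)
    s2 <- drop(t(r) %*% Vi %*% r) / df
    se <- sqrt(s2 * A[ncol(Z), ncol(Z)])
    tv <- bhat[ncol(Z)] / se
    out[j, ] <- c(bhat[ncol(Z)], se, 2 * pt(-abs(tv), df))
  }
  out
}

# two-sided Fisher p by direct enumeration with choose() (independent of
# both the package's dhyper path and stats::fisher.test)
fisher_enum_oracle <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c; N <- m + n2
  if (m == 0 || n2 == 0 || k == 0 || b + d == 0) return(1)
  support <- max(0, k - n2):min(k, m)
  probs <- vapply(support, function(x)
    choose(m, x) * choose(n2, k - x) / choose(N, k), numeric(1))
  p_obs <- probs[support == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# exhaustive permutations by insertion (independent of the package's
# prefix-recursion construction)
permutations_of_oracle <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  prev <- permutations_of_oracle(n - 1L)
  out <- NULL
  for (pos in seq_len(n)) {
    left <- prev[, seq_len(pos - 1L), drop = FALSE]
    right <- prev[, seq_len(n - pos) + (pos - 1L), drop = FALSE]
    out <- rbind(out, cbind(left, n, right))
  }
  out
}

# brute-force union-find merge of intervals (overlap or bookended, same chrom)
union_find_merge <- function(df) {
  # df: chrom, start, end, trait, snps (list)
  n <- nrow(df)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    if (df$chrom[i] == df$chrom[j] &&
        df$start[i] <= df$end[j] + 1L && df$end[i] + 1L >= df$start[j]) {
      parent[find(i)] <- find(j)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comp <- split(seq_len(n), roots)
  out <- lapply(comp, function(ix) {
    list(chrom = df$chrom[ix[1]], start = min(df$start[ix]),
         end = max(df$end[ix]),
         snps = sort(unique(unlist(df$snps[ix]))),
         species = sort(unique(df$trait[ix])))
  })
  ord <- order(vapply(out, `[[`, character(1), "chrom"),
               vapply(out, `[[`, numeric(1), "start"))
  out[ord]
}

# naive agglomerative clustering oracle: recompute linkage from the original
# distance matrix at every step (Lance-Williams-free formulation)
naive_agglom <- function(dm, linkage = "average") {
  n <- nrow(dm)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list(lapply(clusters, identity))
  while (length(clusters) > 1L) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      dd <- dm[clusters[[i]], clusters[[j]], drop = FALSE]
      h <- switch(linkage, average = mean(dd), single = min(dd),
                  complete = max(dd))
      if (h < best[1] - 1e-15) best <- c(h, i, j)
    }
    i <- best[2]; j <- best[3]
    heights <- c(heights, best[1])
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
    partitions[[length(partitions) + 1L]] <- lapply(clusters, identity)
  }
  list(heights = heights, partitions = partitions)
}

# partition agreement up to relabeling
same_partition <- function(a, b) {
  identical(unname(split(seq_along(a), a)[order(vapply(split(seq_along(a), a), min, 1))]),
            unname(split(seq_along(b), b)[order(vapply(split(seq_along(b), b), min, 1))]))
}

# small simulated dataset reused across gwas tests
make_small_study <- function(seed = 1, n_snps = 500, planted = NULL,
                             n_orders = 5, species_per_order = 2, ...) {
  cfg <- simulation_config(n_snps = n_snps, n_orders = n_orders,
                           species_per_order = species_per_order,
                           planted_effects = planted, seed = seed, ...)
  gs <- simulate_genotypes(cfg)
  ab <- simulate_abundances(gs, cfg)
  list(cfg = cfg, geno = gs$genotypes, truth = gs$truth, counts = ab$counts,
       taxonomy = ab$taxonomy, planted = ab$truth)
}
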