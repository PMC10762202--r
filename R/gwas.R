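#' Minor allele frequency per SNP
#'
#' Computed on non-missing calls only.
#'
#' @param genotypes A `genotypes` object or a samples x SNPs dosage matrix.
#' @return Numeric vector of MAFs.
#' @export
snp_maf <- function(genotypes) {
  dos <- if (inherits(genotypes, "genotypes")) genotypes$dosages else genotypes
  f <- colMeans(dos, na.rm = TRUE) / 2
  pmin(f, 1 - f)
}

#' Remove SNPs below a minor-allele-frequency threshold
#'
#' SNPs with MAF strictly below `min_maf` are removed (a SNP at exactly the
#' threshold is kept). MAF is computed on observed calls; missing dosages
#' are left untouched here and mean-imputed later by the kinship and scan
#' steps.
#'
#' @param genotypes A `genotypes` object.
#' @param min_maf Threshold; SNPs with `MAF < min_maf` are dropped.
#' @return The filtered `genotypes` object.
#' @export
filter_maf <- function(genotypes, min_maf = 0.05) {
  keep <- snp_maf(genotypes) >= min_maf
  structure(list(dosages = genotypes$dosages[, keep, drop = FALSE],
                 map = genotypes$map[keep, , drop = FALSE]),
            class = "genotypes")
}

# per-SNP mean imputation of missing dosages
impute_mean <- function(dos) {
  if (!anyNA(dos)) return(dos)
  mu <- colMeans(dos, na.rm = TRUE)
  idx <- which(is.na(dos), arr.ind = TRUE)
  dos[idx] <- mu[idx[, 2]]
  dos
}

#' VanRaden genomic relationship matrix
#'
#' Method 1: dosages are centered by `2 p_k` per SNP (missing values
#' mean-imputed first) and `K = Z Z' / (2 sum(p_k (1 - p_k)))`. Under
#' Hardy-Weinberg equilibrium the diagonal averages approximately 1.
#'
#' @param genotypes A `genotypes` object or dosage matrix.
#' @return Symmetric n x n kinship matrix.
#' @export
vanraden_kinship <- function(genotypes) {
  dos <- if (inherits(genotypes, "genotypes")) genotypes$dosages else genotypes
  dos <- impute_mean(dos)
  p <- colMeans(dos) / 2
  poly <- p > 0 & p < 1 & apply(dos, 2L, stats::sd) > 0
  if (sum(poly) < 2L) stop("need at least two polymorphic SNPs")
  Z <- sweep(dos[, poly, drop = FALSE], 2L, 2 * p[poly])
  K <- tcrossprod(Z) / (2 * sum(p[poly] * (1 - p[poly])))
  (K + t(K)) / 2
}

#' Top principal components of the dosage matrix
#'
#' Structure covariates (Q): the leading principal components of the
#' column-centered, mean-imputed dosage matrix. Signs are fixed so each
#' loading vector's largest-magnitude element is positive.
#'
#' @param genotypes A `genotypes` object or dosage matrix.
#' @param q Number of components; `q = 0` returns a zero-column matrix
#'   ("no structure").
#' @return Samples x q matrix of PC scores.
#' @export
genotype_pcs <- function(genotypes, q = 3L) {
  dos <- if (inherits(genotypes, "genotypes")) genotypes$dosages else genotypes
  if (q < 0) stop("q must be >= 0")
  if (q == 0L)
    return(matrix(numeric(0), nrow(dos), 0L, dimnames = list(rownames(dos), NULL)))
  if (q >= nrow(dos)) stop("q must be smaller than the number of samples")
  dos <- impute_mean(dos)
  pc <- stats::prcomp(dos, center = TRUE, scale. = FALSE, rank. = q)
  scores <- pc$x[, seq_len(q), drop = FALSE]
  for (k in seq_len(q)) {
    j <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[j, k] < 0) scores[, k] <- -scores[, k]
  }
  colnames(scores) <- paste0("PC", seq_len(q))
  scores
}

#' Eigendecomposition of a kinship matrix
#'
#' @param K Symmetric positive-semidefinite kinship matrix.
#' @return List of class `kinship_eigen` with `values` (descending) and
#'   `vectors` (orthonormal columns).
#' @export
kinship_eigen <- function(K) {
  if (max(abs(K - t(K))) > 1e-10) stop("K must be symmetric")
  e <- eigen((K + t(K)) / 2, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(e$values))
    stop("K is not positive semidefinite within tolerance")
  structure(list(values = e$values, vectors = e$vectors),
            class = "kinship_eigen")
}

#' Restricted maximum likelihood fit of the null mixed model
#'
#' Model `y = X beta + u + e` with `u ~ N(0, sigma_g^2 K)` and
#' `e ~ N(0, sigma_e^2 I)`. Writing `delta = sigma_e^2 / sigma_g^2`, the
#' covariance is `sigma_g^2 (K + delta I)`; rotating by the kinship
#' eigenvectors makes it diagonal with per-component variance
#' `lambda_i + delta`. The REML profile likelihood in `delta` is evaluated
#' on a grid over `log10(delta) in [-5, 5]` (101 points) and refined with
#' bounded one-dimensional optimization around the best grid point.
#'
#' @param y Numeric trait vector (no missing values).
#' @param X Fixed-effect design matrix (intercept plus structure
#'   covariates); if `NULL`, an intercept-only design is used.
#' @param Keig A [kinship_eigen()] decomposition.
#' @return List of class `null_model` with `delta`, `sigma_g2`, `sigma_e2`,
#'   `loglik` (REML), `beta` (covariate coefficients) and internals used by
#'   [emmax_scan()].
#' @export
fit_null_reml <- function(y, X = NULL, Keig) {
  stopifnot(inherits(Keig, "kinship_eigen"))
  n <- length(y)
  if (anyNA(y)) stop("missing trait values must be dropped before fitting")
  if (stats::sd(y) == 0) stop("trait is constant")
  if (is.null(X)) X <- matrix(1, n, 1L, dimnames = list(NULL, "intercept"))
  X <- as.matrix(X)
  if (!any(apply(X, 2L, function(col) stats::sd(col) == 0)))
    X <- cbind(intercept = 1, X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("X is collinear")
  p <- ncol(X)
  U <- Keig$vectors
  lam <- pmax(Keig$values, 0)
  yt <- crossprod(U, y)
  Xt <- crossprod(U, X)
  ldet_xx <- determinant(crossprod(X), logarithm = TRUE)$modulus

  reml_ll <- function(log10_delta) {
    delta <- 10^log10_delta
    w <- 1 / (lam + delta)
    sw <- sqrt(w)
    Xw <- Xt * sw
    yw <- yt * sw
    xtx <- crossprod(Xw)
    beta <- solve(xtx, crossprod(Xw, yw))
    r <- yw - Xw %*% beta
    rss <- sum(r^2)
    sg2 <- rss / (n - p)
    -0.5 * ((n - p) * (log(2 * pi * sg2) + 1) - sum(log(w)) +
              determinant(xtx, logarithm = TRUE)$modulus - ldet_xx)
  }
  grid <- seq(-5, 5, length.out = 101L)
  ll <- vapply(grid, reml_ll, numeric(1))
  i <- which.max(ll)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(reml_ll, c(lo, hi), maximum = TRUE, tol = 1e-8)
  best <- if (opt$objective >= ll[i]) opt$maximum else grid[i]
  delta <- 10^best
  w <- 1 / (lam + delta)
  sw <- sqrt(w)
  Xw <- Xt * sw
  yw <- yt * sw
  beta <- solve(crossprod(Xw), crossprod(Xw, yw))
  sg2 <- sum((yw - Xw %*% beta)^2) / (n - p)
  structure(list(delta = delta, sigma_g2 = sg2, sigma_e2 = delta * sg2,
                 loglik = max(opt$objective, ll[i]), beta = drop(beta),
                 grid_loglik = ll, grid = grid, X = X, n = n, p = p),
            class = "null_model")
}

#' EMMAX-style mixed-model association scan
#'
#' Per trait, variance components are estimated once on the null model
#' (the population-parameters-previously-determined approximation); each
#' SNP is then tested by generalized least squares on eigen-rotated data
#' with per-component weights `1/(lambda_i + delta)`. The residual variance
#' is re-estimated per SNP from the GLS fit; `t = beta/se` is referred to a
#' t distribution with `n - rank(X) - 1` degrees of freedom. Missing
#' dosages are mean-imputed; SNPs constant after imputation get `p = 1` and
#' a `degenerate` flag.
#'
#' @param traits Samples x traits numeric matrix (e.g. CSS-log2 values).
#' @param genotypes A `genotypes` object (sample ids must match `traits`
#'   rows).
#' @param Keig [kinship_eigen()] of the kinship matrix.
#' @param Q Structure covariate matrix (samples x q), or `NULL`.
#' @param min_maf SNPs below this MAF are excluded from the scan.
#' @return Data frame with one row per (trait, SNP): `trait`, `snp`,
#'   `chrom`, `pos`, `maf`, `beta`, `se`, `t`, `p`, `df`, `degenerate`.
#'   Attribute `"null_models"` holds the per-trait variance-component fits.
#' @export
emmax_scan <- function(traits, genotypes, Keig, Q = NULL, min_maf = 0.05) {
  traits <- as.matrix(traits)
  dos <- genotypes$dosages
  if (nrow(traits) != nrow(dos))
    stop("trait/genotype sample mismatch")
  if (!is.null(rownames(traits)) && !is.null(rownames(dos)) &&
      !identical(rownames(traits), rownames(dos)))
    stop("trait/genotype sample ids differ")
  g <- filter_maf(genotypes, min_maf)
  G <- impute_mean(g$dosages)
  maf <- snp_maf(g)
  n <- nrow(G)
  U <- Keig$vectors
  lam <- pmax(Keig$values, 0)
  X <- cbind(intercept = rep(1, n), Q)
  p <- ncol(X)
  Gt <- crossprod(U, G)
  Xt <- crossprod(U, X)

  out <- vector("list", ncol(traits))
  nulls <- vector("list", ncol(traits))
  trait_ids <- colnames(traits)
  if (is.null(trait_ids)) trait_ids <- paste0("trait", seq_len(ncol(traits)))
  for (tr in seq_len(ncol(traits))) {
    y <- traits[, tr]
    fit <- fit_null_reml(y, X, Keig)
    nulls[[tr]] <- fit
    sw <- sqrt(1 / (lam + fit$delta))
    yw <- drop(crossprod(U, y)) * sw
    Xw <- Xt * sw
    Gw <- Gt * sw
    xtx_inv <- solve(crossprod(Xw))
    # residualize against covariates under the GLS metric
    Py <- yw - Xw %*% (xtx_inv %*% crossprod(Xw, yw))
    PG <- Gw - Xw %*% (xtx_inv %*% crossprod(Xw, Gw))
    gPg <- colSums(PG * PG)
    gPy <- drop(crossprod(PG, Py))
    yPy <- sum(Py^2)
    df <- n - p - 1L
    degen <- gPg <= max(gPg, 1) * 1e-12
    beta <- ifelse(degen, NA_real_, gPy / gPg)
    rss <- pmax(yPy - ifelse(degen, 0, beta^2 * gPg), 0)
    s2 <- rss / df
    se <- ifelse(degen, NA_real_, sqrt(s2 / gPg))
    tval <- ifelse(degen, 0, beta / se)
    pval <- ifelse(degen, 1, 2 * stats::pt(-abs(tval), df))
    out[[tr]] <- data.frame(
      trait = trait_ids[tr], snp = g$map$snp, chrom = g$map$chrom,
      pos = g$map$pos, maf = maf, beta = beta, se = se, t = tval, p = pval,
      df = df, degenerate = degen, stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  names(nulls) <- trait_ids
  attr(res, "null_models") <- nulls
  res
}

#' Genomic inflation factor
#'
#' Ratio of the median observed association chi-square (obtained from
#' two-sided p-values) to the null median `qchisq(0.5, 1)`.
#'
#' @param p Vector of p-values.
#' @return Scalar inflation factor lambda.
#' @export
genomic_inflation <- function(p) {
  chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}
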