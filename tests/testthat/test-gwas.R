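test_that("MAF filter drops below-threshold SNPs and keeps the boundary", {
  dos <- cbind(
    boundary = c(rep(0L, 90), rep(1L, 10)),   # MAF exactly 0.05
    mono = rep(0L, 100),                      # monomorphic
    common = rep(c(0L, 1L, 2L), length.out = 100)
  )
  rownames(dos) <- paste0("s", 1:100)
  g <- structure(list(dosages = dos,
                      map = data.frame(snp = colnames(dos), chrom = "chr1",
                                       pos = 1:3 * 100L, ref = "A", alt = "G")),
                 class = "genotypes")
  out <- filter_maf(g, 0.05)
  expect_setequal(out$map$snp, c("boundary", "common"))
  # random matrix: surviving set equals brute-force MAF recomputation
  set.seed(1)
  dos2 <- matrix(rbinom(50 * 40, 2, runif(40, 0.02, 0.5)[col(matrix(0, 50, 40))]),
                 50, 40, dimnames = list(NULL, paste0("m", 1:40)))
  g2 <- structure(list(dosages = dos2,
                       map = data.frame(snp = colnames(dos2), chrom = "chr1",
                                        pos = seq_len(40) * 10L, ref = "A",
                                        alt = "G")),
                  class = "genotypes")
  brute <- colnames(dos2)[pmin(colMeans(dos2) / 2, 1 - colMeans(dos2) / 2) >= 0.05]
  expect_identical(filter_maf(g2, 0.05)$map$snp, brute)
})

test_that("VanRaden kinship matches hand arithmetic and scales to ~1 diagonal", {
  dos <- rbind(s1 = c(0L, 2L), s2 = c(1L, 1L), s3 = c(2L, 0L))
  p <- colMeans(dos) / 2
  Z <- sweep(dos, 2, 2 * p)
  K_hand <- Z %*% t(Z) / (2 * sum(p * (1 - p)))
  expect_equal(vanraden_kinship(dos), K_hand, tolerance = 1e-12,
               ignore_attr = TRUE)
  # identical individuals give identical rows with K(i,i) = K(i,j)
  dos2 <- rbind(a = c(0L, 2L, 1L, 1L), b = c(0L, 2L, 1L, 1L),
                c = c(2L, 0L, 0L, 1L), e = c(1L, 1L, 2L, 0L))
  K2 <- vanraden_kinship(dos2)
  expect_equal(K2[1, ], K2[2, ], ignore_attr = TRUE)
  expect_equal(K2[1, 1], K2[1, 2])
  # Hardy-Weinberg simulation: mean diagonal approximately 1
  set.seed(2)
  p <- runif(2000, 0.1, 0.5)
  dosHW <- sapply(p, function(pp) rbinom(200, 2, pp))
  expect_lt(abs(mean(diag(vanraden_kinship(dosHW))) - 1), 0.05)
  expect_error(vanraden_kinship(matrix(1L, 5, 3)), "polymorphic")
})

test_that("genotype PCs separate simulated subpopulations and are orthogonal", {
  cfg <- simulation_config(n_samples = 80, subpop_sizes = c(40, 40),
                           n_snps = 500, fst = 0.2, seed = 3)
  gs <- simulate_genotypes(cfg)
  Q <- genotype_pcs(gs$genotypes, 3)
  lab <- gs$truth$subpop
  # PC1 separates the two subpopulations with no overlap
  r1 <- range(Q[lab == "pop1", 1]); r2 <- range(Q[lab == "pop2", 1])
  expect_true(r1[2] < r2[1] || r2[2] < r1[1])
  expect_equal(crossprod(Q[, 1], Q[, 2])[1], 0, tolerance = 1e-8)
  expect_equal(crossprod(Q[, 1], Q[, 3])[1], 0, tolerance = 1e-8)
  # q = 0 means "no structure"
  expect_equal(ncol(genotype_pcs(gs$genotypes, 0)), 0L)
  expect_error(genotype_pcs(gs$genotypes, 80), "smaller")
})

test_that("kinship eigendecomposition reconstructs K", {
  set.seed(4)
  dos <- sapply(runif(300, 0.1, 0.5), function(p) rbinom(50, 2, p))
  K <- vanraden_kinship(dos)
  Ke <- kinship_eigen(K)
  U <- Ke$vectors
  expect_equal(crossprod(U), diag(50), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(U %*% diag(Ke$values) %*% t(U), K, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_false(is.unsorted(rev(Ke$values)))
  expect_error(kinship_eigen(matrix(c(1, 2, 0, 1), 2)), "symmetric")
})

test_that("REML fit maximizes the profile likelihood and recovers delta", {
  set.seed(5)
  dos <- sapply(runif(800, 0.1, 0.5), function(p) rbinom(300, 2, p))
  # add structure: half the samples from a shifted population
  dos[151:300, 1:200] <- sapply(runif(200, 0.3, 0.7),
                                function(p) rbinom(150, 2, p))
  K <- vanraden_kinship(dos)
  Ke <- kinship_eigen(K)
  deltas <- replicate(25, {
    u <- drop(Ke$vectors %*% (sqrt(pmax(Ke$values, 0)) * rnorm(300)))
    y <- 2 + u + rnorm(300)  # sigma_g2 = 1, sigma_e2 = 1
    fit <- fit_null_reml(y, NULL, Ke)
    expect_gte(fit$loglik, max(fit$grid_loglik) - 1e-9)  # optimizer contract
    fit$delta
  })
  expect_gt(median(deltas), 0.5)
  expect_lt(median(deltas), 2)
  expect_error(fit_null_reml(rep(1, 300), NULL, Ke), "constant")
})

test_that("EMMAX with K = I reproduces ordinary least-squares p-values", {
  st <- make_small_study(seed = 6, n_snps = 100)
  traits <- css_normalize(st$counts)$traits[, 1:3]
  Ke <- kinship_eigen(diag(nrow(traits)))
  scan <- emmax_scan(traits, st$geno, Ke, Q = NULL)
  for (tr in colnames(traits)) {
    for (snp in st$geno$map$snp[c(1, 25, 80)]) {
      fit <- summary(lm(traits[, tr] ~ st$geno$dosages[, snp]))
      row <- scan[scan$trait == tr & scan$snp == snp, ]
      expect_equal(row$p, fit$coefficients[2, 4], tolerance = 1e-8)
      expect_equal(row$beta, fit$coefficients[2, 1], tolerance = 1e-8)
    }
  }
})

test_that("EMMAX p-values match the explicit dense-GLS oracle", {
  st <- make_small_study(seed = 7, n_snps = 300, n_samples = 30,
                         subpop_sizes = c(16, 10, 4))
  traits <- css_normalize(st$counts)$traits[, 1:3]
  g <- st$geno
  K <- vanraden_kinship(g)
  Ke <- kinship_eigen(K)
  Q <- genotype_pcs(g, 2)
  scan <- emmax_scan(traits, g, Ke, Q)
  X <- cbind(1, Q)
  for (tr in colnames(traits)) {
    delta <- attr(scan, "null_models")[[tr]]$delta
    oracle <- gls_oracle(traits[, tr], X, impute_mean_oracle(g$dosages), K, delta)
    got <- scan[scan$trait == tr, ]
    keep <- !got$degenerate
    expect_true(all(abs(log10(got$p[keep]) -
                        log10(oracle[got$snp[keep], "p"])) < 1e-6))
    expect_equal(got$beta[keep], unname(oracle[got$snp[keep], "beta"]),
                 tolerance = 1e-6)
  }
})

test_that("scan output is invariant to sample-order permutation", {
  st <- make_small_study(seed = 8, n_snps = 60, n_samples = 40,
                         subpop_sizes = c(20, 20))
  traits <- css_normalize(st$counts)$traits[, 1:2]
  g <- st$geno
  Ke <- kinship_eigen(vanraden_kinship(g))
  scan <- emmax_scan(traits, g, Ke, genotype_pcs(g, 2))
  set.seed(1)
  perm <- sample(nrow(traits))
  g2 <- structure(list(dosages = g$dosages[perm, ], map = g$map),
                  class = "genotypes")
  Ke2 <- kinship_eigen(vanraden_kinship(g2))
  scan2 <- emmax_scan(traits[perm, , drop = FALSE], g2, Ke2,
                      genotype_pcs(g2, 2))
  expect_equal(scan$p, scan2$p, tolerance = 1e-6)
})

test_that("constant SNPs after imputation are flagged degenerate with p = 1", {
  st <- make_small_study(seed = 9, n_snps = 50, n_samples = 30,
                         subpop_sizes = c(15, 15))
  g <- st$geno
  g$dosages[, 1] <- 1L  # constant
  traits <- css_normalize(st$counts)$traits[, 1, drop = FALSE]
  Ke <- kinship_eigen(vanraden_kinship(g))
  scan <- emmax_scan(traits, g, Ke, NULL, min_maf = 0)
  row <- scan[scan$snp == g$map$snp[1], ]
  expect_true(row$degenerate)
  expect_equal(row$p, 1)
  expect_error(emmax_scan(traits[1:10, , drop = FALSE], g, Ke, NULL),
               "mismatch")
})

test_that("genomic inflation is near 1 under the null chi-square", {
  set.seed(10)
  p <- pchisq(rchisq(20000, 1), 1, lower.tail = FALSE)
  expect_lt(abs(genomic_inflation(p) - 1), 0.05)
})
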