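test_that("Shannon index matches direct evaluation", {
  expect_equal(unname(shannon_index(c(5, 5, 5, 5))), log(4))
  expect_equal(unname(shannon_index(c(10, 0, 0))), 0)
  p <- (1:4) / 10
  expect_equal(unname(shannon_index(c(1, 2, 3, 4))), -sum(p * log(p)),
               tolerance = 1e-12)
  expect_error(shannon_index(c(0, 0)), "all-zero")
})

test_that("Bray-Curtis matches the hand formula and stays in [0,1]", {
  x <- rbind(a = c(1, 2), b = c(3, 0))
  d <- bray_curtis(x)
  expect_equal(d["a", "b"], (2 + 2) / (4 + 2), tolerance = 1e-12)
  expect_equal(d["a", "a"], 0)
  # identical rows -> 0; disjoint supports -> 1
  y <- rbind(u = c(1, 0), v = c(1, 0), w = c(0, 5))
  dy <- bray_curtis(y)
  expect_equal(dy["u", "v"], 0)
  expect_equal(dy["u", "w"], 1)
  # random profiles: symmetric, in [0, 1], equals direct formula
  set.seed(1)
  m <- matrix(runif(40), 4, 10)
  dm <- bray_curtis(m)
  expect_equal(dm, t(dm), tolerance = 1e-12)
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(dm[i, j], sum(abs(m[i, ] - m[j, ])) / sum(m[i, ] + m[j, ]),
                 tolerance = 1e-12)
  expect_error(bray_curtis(rbind(c(0, 0), c(0, 0), c(1, 1))), "all-zero")
})

test_that("PCoA reproduces Euclidean distances (classical-scaling identity)", {
  set.seed(2)
  pts <- matrix(rnorm(30), 10, 3)
  d <- as.matrix(dist(pts))
  ord <- pcoa(d, n_axes = 3)
  rec <- as.matrix(dist(ord$coordinates))
  expect_equal(rec, d, tolerance = 1e-9, ignore_attr = TRUE)
  expect_true(all(diff(ord$eigenvalues) <= 1e-9))
  # proportions over positive eigenvalues only, axes sum <= 1
  expect_true(all(ord$proportion_explained > 0))
  expect_lte(sum(ord$proportion_explained), 1 + 1e-12)
  # sign convention: largest-|coordinate| entry positive per axis
  for (k in seq_len(ncol(ord$coordinates))) {
    j <- which.max(abs(ord$coordinates[, k]))
    expect_gt(ord$coordinates[j, k], 0)
  }
})

test_that("PCoA handles collinear points and duplicate samples", {
  # 3 collinear points with pairwise distances 1, 1, 2: one positive eigenvalue
  d <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3)
  expect_warning(ord <- pcoa(d, n_axes = 2), "positive eigenvalues")
  expect_equal(ncol(ord$coordinates), 1L)
  expect_equal(as.matrix(dist(ord$coordinates)), d, tolerance = 1e-9,
               ignore_attr = TRUE)
  # duplicate samples coincide in the ordination
  x <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(9, 1, 1), e = c(2, 8, 1))
  ord2 <- pcoa(bray_curtis(x), n_axes = 2)
  expect_equal(ord2$coordinates["a", ], ord2$coordinates["b", ],
               tolerance = 1e-9)
})

test_that("PERMANOVA agrees with vegan and with exhaustive enumeration", {
  set.seed(3)
  m <- matrix(runif(6 * 8), 6, 8, dimnames = list(paste0("s", 1:6), NULL))
  groups <- factor(rep(c("A", "B"), each = 3))
  d <- bray_curtis(m)
  res <- permanova(d, groups, n_perm = 199, seed = 5)
  # F and R2 cross-checked against vegan::adonis2
  ad <- vegan::adonis2(as.dist(d) ~ groups)
  expect_equal(res$F, ad$F[1], tolerance = 1e-10)
  expect_equal(res$R2, ad$R2[1], tolerance = 1e-10)
  expect_true(res$R2 >= 0 && res$R2 <= 1)
  # p from exhaustive relabeling equals direct enumeration over all 720
  exact <- permanova(d, groups, exact = TRUE)
  perms <- permutations_of_oracle(6)
  d2 <- d^2
  fstat <- function(g) {
    sst <- sum(d2[upper.tri(d2)]) / 6
    ssw <- 0
    for (lev in levels(g)) {
      ix <- which(g == lev)
      ssw <- ssw + sum(d2[ix, ix][upper.tri(d2[ix, ix])]) / length(ix)
    }
    ((sst - ssw) / 1) / (ssw / 4)
  }
  f_all <- apply(perms, 1, function(ix) fstat(groups[ix]))
  expect_equal(exact$p, mean(f_all >= fstat(groups) - 1e-12))
  expect_equal(exact$n_perm, 720)
})

test_that("PERMANOVA p has resolution 1/(n_perm+1) and detects planted shifts", {
  set.seed(4)
  base <- matrix(runif(20 * 10), 20, 10)
  groups <- factor(rep(c("A", "B"), each = 10))
  shifted <- base
  shifted[groups == "B", 1:5] <- shifted[groups == "B", 1:5] + 2
  d <- bray_curtis(shifted)
  res <- permanova(d, groups, n_perm = 99, seed = 1)
  expect_equal(res$p, 1 / 100)  # smallest attainable p at 99 permutations
  expect_true(res$p * 100 == round(res$p * 100))
  # shuffled labels give lower R2 than the true labels
  set.seed(9)
  res_shuf <- permanova(d, sample(groups), n_perm = 99, seed = 1)
  expect_gt(res$R2, res_shuf$R2)
  # determinism under a fixed seed
  expect_identical(permanova(d, groups, n_perm = 99, seed = 7),
                   permanova(d, groups, n_perm = 99, seed = 7))
  expect_error(permanova(d, factor(rep("A", 20))), "two groups")
  expect_error(permanova(d, factor(c("A", rep("B", 19)))), "at least two samples")
})

test_that("PERMANOVA p is approximately uniform on exchangeable data", {
  set.seed(5)
  ps <- replicate(40, {
    m <- matrix(runif(12 * 6), 12, 6)
    permanova(bray_curtis(m), factor(rep(c("A", "B"), each = 6)),
              n_perm = 59, seed = sample.int(1e6, 1))$p
  })
  # calibration: mean of a uniform p is 0.5; wide tolerance for 40 reps
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.7)
  expect_gt(mean(ps <= 0.2), 0.05)
})

test_that("rank-sum test matches exact enumeration and survives monotone maps", {
  vals <- cbind(t1 = c(1, 2, 3, 10, 11, 12), t2 = c(5, 1, 4, 2, 6, 3))
  rownames(vals) <- paste0("s", 1:6)
  groups <- factor(rep(c("A", "B"), each = 3))
  res <- differential_abundance(vals, groups, "wilcoxon")
  # (1,2,3) vs (10,11,12): most extreme of choose(6,3)=20 assignments -> p = 2/20
  expect_equal(res$p[res$taxon == "t1"], 0.1)
  # invariance under strictly monotone transform
  res_log <- differential_abundance(log1p(vals), groups, "wilcoxon")
  expect_equal(res$p, res_log$p)
  expect_equal(res$stat, res_log$stat)
  # BH never decreases p and equal p-values share the adjusted value
  expect_true(all(res$p_adj >= res$p))
  m <- cbind(a = c(1, 2, 3, 10, 11, 12), b = c(3, 2, 1, 12, 11, 10))
  res2 <- differential_abundance(m, groups, "wilcoxon")
  expect_equal(res2$p_adj[1], res2$p_adj[2])
})

test_that("ANOVA/Tukey path reports F, Tukey pairs and BH adjustment", {
  set.seed(6)
  vals <- cbind(null = rnorm(12),
                shifted = c(rnorm(4), rnorm(4) + 3, rnorm(4) + 6))
  rownames(vals) <- paste0("s", 1:12)
  groups <- factor(rep(c("A", "B", "C"), each = 4))
  res <- differential_abundance(vals, groups, "anova_tukey")
  expect_true(all(c("mean_A", "mean_B", "mean_C") %in% names(res)))
  expect_true(any(grepl("^tukey_", names(res))))
  # oracle: stats::aov on the shifted taxon
  fit <- aov(vals[, "shifted"] ~ groups)
  expect_equal(res$p[res$taxon == "shifted"], summary(fit)[[1]][1, "Pr(>F)"])
  expect_lt(res$p[res$taxon == "shifted"], 0.001)
  expect_gt(res$p[res$taxon == "null"], 0.01)
  expect_error(differential_abundance(vals, factor(c("A", rep(c("B", "C"), c(5, 6)))),
                                      "anova_tukey"), ">= 2 samples")
})
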