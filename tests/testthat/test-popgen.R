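test_that("HWE exact test matches full enumeration", {
  expect_equal(hwe_exact_test(5, 0, 0), 1)     # monomorphic
  expect_equal(hwe_exact_test(0, 0, 7), 1)
  expect_equal(hwe_exact_test(1, 0, 1), 1 / 3) # only het in {0, 2}
  set.seed(4)
  for (i in 1:25) {
    cnt <- as.vector(rmultinom(1, sample(4:30, 1), c(0.3, 0.4, 0.3)))
    expect_equal(hwe_exact_test(cnt[1], cnt[2], cnt[3]),
                 hwe_brute(cnt[1], cnt[2], cnt[3]), tolerance = 1e-12)
  }
})

test_that("site filters remove the enumerated sites step by step", {
  g <- make_toy_geno()
  out <- filter_sites(g)
  rep <- out$report
  expect_equal(rep$removed[rep$step == "depth_low"], 3)
  expect_equal(rep$removed[rep$step == "mac"], 3)
  expect_equal(rep$removed[rep$step == "missing_site_pass1"], 3)
  expect_equal(ncol(out$geno$geno), 1)
  expect_equal(colnames(out$geno$geno), "s10")
  # removal counts account for every lost site
  expect_equal(sum(rep$removed), 10 - ncol(out$geno$geno))

  # all-passing matrix is untouched
  clean <- cbind(s1 = c(0L, 1L, 2L, 1L, 0L, 1L, 2L, 1L),
                 s2 = c(2L, 1L, 0L, 1L, 2L, 1L, 0L, 1L))
  rownames(clean) <- sprintf("i%d", 1:8)
  g2 <- geno_matrix(clean, depth = c(20, 25), pop = factor(rep("A", 8)))
  out2 <- filter_sites(g2)
  expect_equal(out2$geno$geno, g2$geno)
  expect_equal(sum(out2$report$removed), 0)

  # mac boundary: count 2 removed, count 3 retained
  geno <- cbind(s_mac2 = c(1L, 1L, rep(0L, 6)),
                s_mac3 = c(1L, 1L, 1L, rep(0L, 5)))
  rownames(geno) <- sprintf("i%d", 1:8)
  g3 <- geno_matrix(geno, depth = c(20, 20),
                    pop = factor(rep("A", 8)))
  out3 <- filter_sites(g3)
  expect_equal(colnames(out3$geno$geno), "s_mac3")
})

test_that("HWE filter drops a site failing in any single species", {
  # species A in exact HWE, species B with a massive heterozygote deficit
  set.seed(5)
  nA <- 40; nB <- 40
  sA <- c(rep(0L, 10), rep(1L, 20), rep(2L, 10))
  sB <- c(rep(0L, 20), rep(2L, 20))
  bad <- c(sA, sB)
  ok <- c(sA, sA)
  g <- geno_matrix(cbind(bad = bad, ok = ok), depth = c(20, 20),
                   pop = factor(rep(c("A", "B"), c(nA, nB))),
                   species = factor(rep(c("A", "B"), c(nA, nB))))
  out <- filter_sites(g)
  expect_equal(colnames(out$geno$geno), "ok")
  expect_equal(out$report$removed[out$report$step == "hwe"], 1)
})

test_that("imputation fills with the species mode, ties to the lower code", {
  geno <- rbind(c(0L, 0L, 0L), c(0L, 0L, 2L), c(2L, 2L, 2L),
                c(NA, 2L, NA), c(0L, NA, 2L))
  dimnames(geno) <- list(sprintf("i%d", 1:5), sprintf("s%d", 1:3))
  g <- geno_matrix(geno, depth = rep(10, 3), pop = factor(rep("A", 5)),
                   species = factor(rep("A", 5)))
  gi <- impute_major(g)
  expect_equal(gi$geno["i4", "s1"], 0L)  # mode of {0,0,2,0} is 0
  expect_equal(gi$geno["i5", "s2"], 0L)  # mode of {0,0,2,2} ties -> 0
  expect_equal(gi$geno["i4", "s3"], 2L)  # mode of {0,2,2,2} is 2
  expect_false(anyNA(gi$geno))
  expect_equal(attr(gi, "n_ties"), 1L)
  # identity on complete data
  expect_identical(impute_major(gi)$geno, gi$geno)
  # an all-missing species-site cell is an error naming it
  geno[, 1] <- NA
  g2 <- geno_matrix(geno, depth = rep(10, 3), pop = factor(rep("A", 5)),
                    species = factor(rep("A", 5)))
  expect_error(impute_major(g2), "A:s1")
})

test_that("PCA matches the covariance-eigen oracle and is centering-invariant", {
  set.seed(6)
  G <- matrix(rbinom(30 * 50, 2, 0.4), 30, 50)
  p <- pca_genotypes(G, n_axes = 5)
  ev <- eigen(cov(G), symmetric = TRUE)$values
  expect_equal(p$pct_var, 100 * ev[1:5] / sum(ev), tolerance = 1e-8)
  expect_lte(sum(p$pct_var), 100 + 1e-8)
  # adding a constant to one column changes nothing
  G2 <- G
  G2[, 3] <- G2[, 3] + 7
  p2 <- pca_genotypes(G2, n_axes = 5)
  expect_equal(abs(p2$scores), abs(p$scores), tolerance = 1e-8)
  # duplicated single direction: PC1 carries all variance
  base <- rbinom(30, 2, 0.5)
  G3 <- matrix(rep(base, 10), 30, 10)
  p3 <- suppressWarnings(pca_genotypes(G3, n_axes = 2))
  expect_equal(p3$pct_var[1], 100, tolerance = 1e-8)
})

test_that("partial RDA matches a brute-force projection oracle", {
  set.seed(7)
  n <- 10
  Y <- matrix(rnorm(n * 20), n, 20)
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  r <- partial_rda(Y, X)
  # oracle: hat-matrix projection on the centered design
  Xc <- scale(X, scale = FALSE)
  H <- Xc %*% solve(crossprod(Xc)) %*% t(Xc)
  Yc <- scale(Y, scale = FALSE)
  expect_equal(r$prop_constrained, sum((H %*% Yc)^2) / sum(Yc^2),
               tolerance = 1e-10)
  # with conditioning: raw fractions sum to one
  C <- cbind(rnorm(n))
  r2 <- partial_rda(Y, X, condition = C)
  expect_equal(r2$prop_conditional + r2$prop_constrained + r2$prop_residual,
               1, tolerance = 1e-10)
  # exact linear response: R2 = 1 and the causal loading dominates axis 1
  Yl <- outer(X[, 1], rnorm(20))
  r3 <- partial_rda(Yl, X)
  expect_equal(r3$prop_constrained, 1, tolerance = 1e-9)
  expect_gt(abs(r3$loadings["x1", 1]), 0.99)
})

test_that("partial RDA agrees with the vegan implementation", {
  skip_if_not_installed("vegan")
  set.seed(8)
  n <- 40
  Y <- matrix(rbinom(n * 60, 2, 0.3), n, 60)
  X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  C <- data.frame(pc1 = rnorm(n), pc2 = rnorm(n))
  mine <- partial_rda(Y, as.matrix(X), condition = as.matrix(C))
  vg <- vegan::rda(Y ~ a + b + c + Condition(pc1 + pc2),
                   data = cbind(X, C))
  adj <- vegan::RsquareAdj(vg)
  expect_equal(mine$adj_r2_constrained, adj$adj.r.squared, tolerance = 1e-8)
  expect_equal(mine$prop_constrained,
               vg$CCA$tot.chi / vg$tot.chi, tolerance = 1e-8)
  expect_equal(sort(mine$eig, decreasing = TRUE)[1:3] / mine$ss_total,
               unname(vg$CCA$eig[1:3]) / vg$tot.chi, tolerance = 1e-8)
})

test_that("permutation tests saturate under planted association and keep the +1 floor", {
  set.seed(9)
  n <- 30
  X <- cbind(x = rnorm(n))
  Y <- outer(X[, 1], rnorm(40)) + matrix(rnorm(n * 40, 0, 0.01), n, 40)
  r <- partial_rda(Y, X)
  pa <- permutation_anova(r, n_perm_model = 99, n_perm_axis = 49, seed = 1)
  expect_equal(pa$p_model, 1 / 100)
  expect_equal(unname(pa$p_axis[1]), 1 / 50)
  # reproducible under a fixed seed
  pb <- permutation_anova(r, n_perm_model = 99, n_perm_axis = 49, seed = 1)
  expect_identical(pa, pb)
})

test_that("Monte-Carlo model p matches full enumeration on a 4-individual case", {
  set.seed(10)
  n <- 4
  X <- cbind(x = rnorm(n))
  Y <- matrix(rnorm(n * 6), n, 6)
  r <- partial_rda(Y, X)
  # exact null distribution over all 4! row permutations
  f_all <- vapply(all_perms(4), function(p) {
    Xp <- X[p, , drop = FALSE]
    qx <- qr(scale(Xp, scale = FALSE))
    ssf <- sum(qr.fitted(qx, r$Yred)^2)
    (ssf / r$p) / ((sum(r$Yred^2) - ssf) / r$df_res)
  }, numeric(1))
  p_exact <- mean(f_all >= r$pseudo_f - 1e-12)
  pa <- permutation_anova(r, n_perm_model = 999, n_perm_axis = 0, seed = 2)
  expect_lt(abs(pa$p_model - p_exact),
            4 * sqrt(p_exact * (1 - p_exact) / 999) + 2 / 999)
})

test_that("variance partitioning finds the planted variable and guards VIF", {
  cfg <- sim_config(seed = 31, genotype = list(n_loci = 800))
  gea <- gen_gea_dataset(cfg)
  gi <- impute_major(gea$geno)
  pca <- pca_genotypes(gi, 4)
  idx <- match(gea$locality, gea$bioclim$site)
  clim <- sapply(gea$clim_vars,
                 function(v) standardize_2sd(gea$bioclim[[v]][idx]))
  vp <- variance_partition(gi$geno, clim, condition = pca$scores[, 1:2])
  frac <- setNames(vp$adj_r2[1:8], vp$component[1:8])
  expect_equal(names(which.max(frac)), "bio7")
  expect_lte(sum(frac), vp$adj_r2[vp$component == "constrained_total"] + 0.02)
  # a duplicated variable trips the VIF guard
  clim_dup <- cbind(clim, bio7b = clim[, "bio7"] + rnorm(nrow(clim), 0, 1e-4))
  expect_error(partial_rda(gi$geno, clim_dup,
                           condition = pca$scores[, 1:2]), "VIF")
})

test_that("weighted Weir's theta reproduces hand-computed components", {
  # 2 pops x 5 diploids, p = 0.9 vs 0.1, one heterozygote each:
  # nbar = 5, nc = 5, pbar = 0.5, s2 = 0.32, hbar = 0.2
  # a = 0.31, b = 0, c = 0.1, theta = 0.31 / 0.41
  geno <- rbind(matrix(c(2L, 2L, 2L, 2L, 1L), 5, 1),
                matrix(c(0L, 0L, 0L, 0L, 1L), 5, 1))
  rownames(geno) <- sprintf("i%d", 1:10)
  colnames(geno) <- "s1"
  w <- weir_theta(geno, rep(c("P1", "P2"), each = 5))
  expect_equal(unname(w$components), c(0.31, 0, 0.1), tolerance = 1e-10)
  expect_equal(w$theta, 0.31 / 0.41, tolerance = 1e-10)

  # fixed difference, no heterozygotes: theta = 1
  geno2 <- cbind(s1 = c(rep(0L, 5), rep(2L, 5)))
  rownames(geno2) <- sprintf("i%d", 1:10)
  expect_equal(weir_theta(geno2, rep(c("P1", "P2"), each = 5))$theta, 1)

  # identical populations built so the among-population component vanishes
  geno3 <- cbind(s1 = rep(1L, 10), s2 = rep(1L, 10))
  rownames(geno3) <- sprintf("i%d", 1:10)
  w3 <- weir_theta(geno3, rep(c("P1", "P2"), each = 5))
  expect_lt(abs(w3$theta), 1e-12)

  # allele-label swap (0 <-> 2) leaves theta unchanged
  set.seed(11)
  geno4 <- matrix(rbinom(200, 2, 0.4), 20, 10,
                  dimnames = list(sprintf("i%d", 1:20), NULL))
  pop <- rep(c("P1", "P2"), each = 10)
  expect_equal(weir_theta(2L - geno4, pop)$theta,
               weir_theta(geno4, pop)$theta, tolerance = 1e-12)
})

test_that("VIF and correlation pruning behave on constructed sets", {
  set.seed(12)
  # columns orthogonal to each other and to the intercept: all VIFs 1
  X <- qr.Q(qr(cbind(1, matrix(rnorm(40 * 3), 40, 3))))[, 2:4]
  colnames(X) <- c("a", "b", "c")
  expect_equal(unname(vif(X)), rep(1, 3), tolerance = 1e-8)
  # x and 2x prune to a single variable
  x <- rnorm(30)
  pr <- correlation_prune(cbind(a = x, b = 2 * x, c = rnorm(30)))
  expect_equal(length(pr$keep), 2)
  expect_true("c" %in% pr$keep)
  expect_equal(length(pr$dropped), 1)
  # pruned set is exactly the r < 0.70 maximal retained set for this fixture
  y <- x + rnorm(30, 0, 0.1)   # r(x, y) >> 0.7
  z <- rnorm(30)
  pr2 <- correlation_prune(cbind(x = x, y = y, z = z))
  expect_equal(sort(pr2$keep), sort(c(setdiff(c("x", "y"), pr2$dropped), "z")))
  expect_true(all(abs(cor(cbind(x = x, y = y, z = z)[, pr2$keep])
                      [upper.tri(diag(2))]) < 0.70))
})

test_that("genotypes round-trip through VCF and matrix CSV", {
  cfg <- sim_config(seed = 32, genotype = list(n_loci = 40, n_adaptive = 10,
                                               n_per_pop = 4))
  g <- gen_genotypes(cfg)
  d <- withr::local_tempdir()
  vcf <- file.path(d, "g.vcf")
  write_geno_vcf(g, vcf)
  pm <- data.frame(id = rownames(g$geno), pop = as.character(g$pop))
  g2 <- read_geno_vcf(vcf, popmap = pm)
  expect_equal(unname(g2$geno[rownames(g$geno), ]), unname(g$geno))
  expect_equal(g2$depth, round(g$depth, 3), tolerance = 1e-9)
  csv <- file.path(d, "g.csv")
  write_geno_matrix(g, csv)
  g3 <- read_geno_matrix(csv)
  expect_equal(unname(g3$geno), unname(g$geno))
  expect_equal(as.character(g3$pop), as.character(g$pop))
})
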