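test_that("F_ST covariance has the documented limits and stays PSD", {
  pops <- c("p1", "p2", "p3")
  z <- matrix(0, 3, 3, dimnames = list(pops, pops))
  expect_equal(unname(fst_covariance(z)$S), matrix(1, 3, 3))
  near1 <- matrix(0.999, 3, 3, dimnames = list(pops, pops))
  diag(near1) <- 0
  S <- fst_covariance(near1)$S
  expect_equal(unname(diag(S)), rep(1, 3))
  expect_lt(max(abs(S[upper.tri(S)])), 0.01)
  # non-PSD raw similarity gets clipped to PSD with unit diagonal
  th <- matrix(c(0, 0.02, 0.9,
                 0.02, 0, 0.02,
                 0.9, 0.02, 0), 3, 3, dimnames = list(pops, pops))
  out <- fst_covariance(th)
  ev <- eigen(out$S, symmetric = TRUE)$values
  expect_gte(min(ev), -1e-12)
  expect_equal(unname(diag(out$S)), rep(1, 3))
  # expansion to individuals follows membership
  out2 <- fst_covariance(z, pops = c("p1", "p1", "p3"))
  expect_equal(dim(out2$S_ind), c(3, 3))
  expect_error(fst_covariance(z, pops = "p9"), "p9")
  # kernel mode: zero distance means similarity one
  expect_equal(unname(diag(fst_covariance(z, mode = "kernel")$S)), rep(1, 3))
})

test_that("Gibbs posterior matches the conjugate closed form without random effects", {
  set.seed(17)
  n <- 80
  X <- cbind(`(Intercept)` = 1, x1 = rnorm(n), x2 = rnorm(n))
  beta_true <- c(1, 2, -0.5)
  y <- drop(X %*% beta_true) + rnorm(n, 0, 0.7)
  fit <- gibbs_lmm(y, X, n_iter = 4e4, burn_in = 4e3, thin = 10, seed = 18,
                   fix_sigma2_u = 0)
  # closed form: essentially the OLS solution under the diffuse prior
  bhat <- solve(crossprod(X) + diag(1e-8, 3), crossprod(X, y))
  mcse <- apply(fit$samples[, 1:3], 2, sd) / sqrt(fit$n_samples / 3)
  for (j in 1:3)
    expect_lt(abs(fit$fixed$mean[j] - bhat[j]), 5 * mcse[j] + 1e-4)
  # residual-variance posterior mean matches the inverse-gamma closed form
  rss <- sum(lm.fit(X, y)$residuals^2)
  an <- 0.001 + (n) / 2
  # marginalized form is close to rss/(n - p - 2) for diffuse priors
  expect_equal(unname(fit$sigma2_e[["mean"]]), rss / (n - 3 - 2),
               tolerance = 0.08)
  # constant response: intercept concentrates there, slopes at zero
  fit0 <- gibbs_lmm(rep(5, 30), cbind(1, rnorm(30)), n_iter = 5e3,
                    burn_in = 500, thin = 5, seed = 19, fix_sigma2_u = 0)
  expect_equal(fit0$fixed$mean[1], 5, tolerance = 1e-3)
  expect_equal(fit0$fixed$mean[2], 0, tolerance = 1e-3)
})

test_that("pMCMC has the 2-tail definition, the floor, and null uniformity", {
  set.seed(20)
  n <- 40
  hits <- 0
  n_rep <- 50
  for (i in seq_len(n_rep)) {
    X <- cbind(1, x = rnorm(n))
    y <- rnorm(n)  # slope truly zero
    fit <- gibbs_lmm(y, X, n_iter = 6e3, burn_in = 1e3, thin = 5,
                     fix_sigma2_u = 0)
    pm <- fit$fixed$pMCMC[2]
    s <- fit$samples[, 2]
    expect_equal(pm, max(2 * min(mean(s > 0), mean(s < 0)),
                         1 / fit$n_samples))
    hits <- hits + (pm <= 0.05)
  }
  # type-I error compatible with the nominal 5% level
  expect_lte(hits, qbinom(0.995, n_rep, 0.05) + 1)
})

test_that("the delta model recovers a planted interaction and respects coding", {
  cfg <- sim_config(seed = 33)
  acc <- gen_acclimation_dataset(cfg)
  post <- fit_delta_model(acc$records, acc$fst, n_iter = 5e4,
                          burn_in = 5e3, thin = 25, seed = 21)
  row <- post$fixed[post$fixed$term == "cold:trange_std", ]
  expect_lt(row$l95, row$u95)
  expect_true(row$l95 <= 0.60 && 0.60 <= row$u95)
  expect_lt(row$pMCMC, 0.05)
  # flipping the treatment coding flips the treatment effect's sign
  rec2 <- acc$records
  rec2$treatment <- ifelse(rec2$treatment == "cold", "control", "cold")
  rec2$post_msum <- acc$records$post_msum
  post2 <- fit_delta_model(rec2, acc$fst, n_iter = 5e4,
                           burn_in = 5e3, thin = 25, seed = 21)
  b1 <- post$fixed$mean[post$fixed$term == "cold"]
  b2 <- post2$fixed$mean[post2$fixed$term == "cold"]
  expect_lt(abs(b1 + b2), 0.15)  # equal magnitude, opposite sign (MC error)
})

test_that("planted-null fixed effects stay non-significant", {
  nulls <- 0
  n_rep <- 10
  for (s in seq_len(n_rep)) {
    cfg <- sim_config(seed = 200 + s,
                      acclimation = list(beta0 = 0, beta_mb = 0,
                                         beta_treat = 0, beta_int = 0,
                                         resid_log_sd_slope = 0))
    acc <- gen_acclimation_dataset(cfg)
    post <- fit_delta_model(acc$records, acc$fst, n_iter = 2e4,
                            burn_in = 2e3, thin = 20, seed = s)
    pm <- post$fixed$pMCMC[post$fixed$term == "cold:trange_std"]
    nulls <- nulls + (pm > 0.05)
  }
  expect_gte(nulls, ceiling(0.9 * n_rep) - 1)
})

test_that("CV is scale-invariant, zero for constants, and matches the closed form", {
  expect_equal(cv_percent(c(2, 4)), 100 * sqrt(2) / 3, tolerance = 1e-10)
  expect_equal(cv_percent(rep(3.3, 5)), 0)
  set.seed(22)
  x <- rlnorm(20)
  expect_equal(cv_percent(3.7 * x), cv_percent(x), tolerance = 1e-10)
  expect_warning(out <- cv_percent(c(-1, 1)), "undefined")
  expect_true(is.na(out))
  expect_error(cv_percent(1), "n >= 2")
})

test_that("CV regression matches the closed form and recovers the planted sign", {
  cv <- c(120, 80, 60, 30, 20)
  tr <- c(24, 27, 33, 39, 45)
  out <- cv_vs_trange(cv, tr)
  beta <- cov(cv, tr) / var(tr)
  expect_equal(out$beta, beta, tolerance = 1e-12)
  expect_equal(out$r2, cor(cv, tr)^2, tolerance = 1e-12)
  expect_equal(cv_vs_trange(2 * tr + 3, tr)$r2, 1)
  negs <- 0
  n_rep <- 10
  for (s in seq_len(n_rep)) {
    acc <- gen_acclimation_dataset(sim_config(seed = 300 + s))
    r <- acc$records
    r$delta <- r$post_msum - r$pre_msum
    cold <- r[r$treatment == "cold", ]
    cvs <- vapply(split(cold, cold$population, drop = TRUE),
                  function(d) cv_percent(d$delta), numeric(1))
    trs <- vapply(split(cold, cold$population, drop = TRUE),
                  function(d) d$trange[1], numeric(1))
    negs <- negs + (cv_vs_trange(cvs, trs)$beta < 0)
  }
  expect_gte(negs, ceiling(0.9 * n_rep) - 1)
})

test_that("paired t-test matches the hand calculation", {
  out <- paired_ttest(rep(0, 4), c(1, 2, 3, 4))
  expect_equal(out$t, 3.872983, tolerance = 1e-6)
  expect_equal(out$df, 3)
  expect_equal(out$p, 2 * pt(-3.872983, 3), tolerance = 1e-6)
  z <- paired_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(z$t, 0)
  expect_equal(z$p, 1)
  expect_equal(paired_ttest(c(0, 0), c(1, -1))$t, 0)
})

test_that("pre-acclimation companion checks run and find the planted T_range effect", {
  acc <- gen_acclimation_dataset(sim_config(seed = 34))
  pre <- fit_pre_checks(acc$records, acc$fst, n_iter = 1.5e4,
                        burn_in = 2e3, thin = 15, seed = 23)
  expect_named(pre, c("msum_treatment", "mb_treatment", "msum_trange",
                      "mb_trange", "msum_season"))
  # treatment groups were randomized: no pre-acclimation difference
  expect_gt(pre$msum_treatment$fixed$pMCMC[2], 0.05)
  # the generator plants a positive T_range effect on pre-acclimation M_sum
  expect_gt(pre$msum_trange$fixed$mean[2], 0)
  expect_lt(pre$msum_trange$fixed$pMCMC[2], 0.05)
})
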