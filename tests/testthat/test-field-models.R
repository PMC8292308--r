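make_field_fixture <- function(seed = 20, n = 40, resid_sd = 0.3,
                               slopes = c(oreganus = 0.05, mearnsi = 0.12)) {
  set.seed(seed)
  taxa <- names(slopes)
  d <- data.frame(id = sprintf("i%03d", seq_len(n * length(taxa))),
                  taxon = rep(taxa, each = n))
  d$mass <- rnorm(nrow(d), 19, 1.2)
  d$env <- rnorm(nrow(d), 10, 3)
  d$msum <- 1 + 0.5 * d$mass + slopes[d$taxon] * d$env +
    rnorm(nrow(d), 0, resid_sd)
  env <- data.frame(id = d$id, window = 8, x = d$env)
  list(pheno = d[, c("id", "taxon", "msum", "mass")], env = env, d = d)
}

test_that("field model matches the normal-equations oracle", {
  fx <- make_field_fixture()
  fm <- fit_field_model(fx$pheno, fx$env, "x", 8)
  # oracle: explicit least squares via pseudo-inverse on the same design
  X <- model.matrix(~ mb_std + taxon * env_std, data = fm$data)
  beta <- solve(crossprod(X), crossprod(X, fm$data$msum))
  expect_equal(unname(coef(fm$fit)), as.numeric(beta), tolerance = 1e-8)
  expect_equal(fm$aic, AIC(fm$fit))
  expect_equal(fm$n, nrow(fm$data))
})

test_that("noiseless data recover planted raw slopes through the back-transform", {
  fx <- make_field_fixture(resid_sd = 0)
  fm <- fit_field_model(fx$pheno, fx$env, "x", 8)
  norms <- reaction_norm_slopes(fm)
  expect_equal(norms$slope_raw[norms$taxon == "oreganus"], 0.05,
               tolerance = 1e-9)
  expect_equal(norms$slope_raw[norms$taxon == "mearnsi"], 0.12,
               tolerance = 1e-9)
  # rescaling the variable leaves raw slopes unchanged
  fx2 <- fx
  fx2$env$x <- fx2$env$x * 10
  norms2 <- reaction_norm_slopes(fit_field_model(fx2$pheno, fx2$env, "x", 8))
  expect_equal(norms2$slope_raw * 10, norms$slope_raw, tolerance = 1e-9)
})

test_that("reaction norms agree with per-taxon stratified regressions", {
  # with the shared mass term removed, the full interaction model is
  # exactly separable into per-taxon simple regressions
  fx <- make_field_fixture(seed = 21, resid_sd = 0.4)
  d <- fx$d
  d$env_std <- standardize_2sd(d$env)
  d$taxon <- relevel(factor(d$taxon), "oreganus")
  fit <- lm(msum ~ taxon * env_std, data = d)
  sd_raw <- attr(d$env_std, "scale_sd")
  slope_std <- c(
    oreganus = coef(fit)[["env_std"]],
    mearnsi = coef(fit)[["env_std"]] + coef(fit)[["taxonmearnsi:env_std"]]
  )
  for (tx in c("oreganus", "mearnsi")) {
    strat <- coef(lm(msum ~ env, data = d[d$taxon == tx, ]))[["env"]]
    expect_equal(unname(slope_std[tx]) / (2 * sd_raw), strat,
                 tolerance = 1e-6)
  }
})

test_that("AIC bookkeeping: nested identical fits differ by 2 per parameter", {
  fx <- make_field_fixture(seed = 22)
  d <- fx$d
  f1 <- lm(msum ~ mass, data = d)
  set.seed(1)
  # a regressor orthogonal to the design AND the residuals gets a zero
  # coefficient: identical fit, one extra parameter
  v <- rnorm(nrow(d))
  d$junk <- resid(lm(v ~ d$mass + resid(f1)))
  f2 <- lm(msum ~ mass + junk, data = d)
  expect_equal(AIC(f2) - AIC(f1), 2, tolerance = 1e-6)
})

test_that("model selection ranks the planted window first and books elevation once", {
  cfg <- sim_config(seed = 30)
  fd <- gen_field_dataset(cfg)
  env <- build_env_features(fd$pheno, fd$weather, windows = 7:9,
                            sites = fd$sites)
  sel <- select_model(fd$pheno, env, windows = 7:9)
  expect_equal(sel$ranking$variable[1], "t_d_range")
  expect_equal(sel$ranking$window[1], 8)
  expect_equal(sum(sel$ranking$variable == "elev"), 1)
  expect_true(is.na(sel$ranking$window[sel$ranking$variable == "elev"]))
  expect_true("null" %in% sel$ranking$variable)
  expect_gt(sel$delta_aic_interaction, 0)
})

test_that("null simulations keep the null model competitive", {
  # no environmental effect at all: the null model should sit within
  # Delta-AIC 2 of the best candidate in most replicates (reduced
  # candidate set keeps the max-of-chi-square excursion small)
  hits_null <- 0
  hits_int <- 0
  n_rep <- 15
  for (s in seq_len(n_rep)) {
    cfg <- sim_config(seed = 100 + s,
                      field = list(slopes = rep(0, 5), n_per_taxon = 40,
                                   n_sites_per_taxon = 2))
    fd <- gen_field_dataset(cfg)
    env <- build_env_features(fd$pheno, fd$weather, windows = 7:9,
                              sites = fd$sites,
                              variables = c("tmin", "prcp", "t_d_range"))
    sel <- select_model(fd$pheno, env, windows = 7:9,
                        variables = c("tmin", "prcp", "t_d_range"))
    null_aic <- sel$ranking$aic[sel$ranking$variable == "null"]
    hits_null <- hits_null + (null_aic - min(sel$ranking$aic) <= 2)
    # equal (zero) slopes: interaction must not be favored by > 4 AIC
    hits_int <- hits_int + (sel$delta_aic_interaction <= 4)
  }
  expect_gte(hits_null, ceiling(0.8 * n_rep))
  expect_gte(hits_int, ceiling(0.9 * n_rep))
})

test_that("flexibility regression matches the closed-form simple regression", {
  norms <- data.frame(taxon = letters[1:5],
                      slope_raw = c(0.02, 0.05, 0.03, 0.09, 0.07))
  tr <- c(a = 24, b = 31, c = 28, d = 45, e = 39)
  out <- flexibility_vs_heterogeneity(norms, tr)
  x <- tr[norms$taxon]; y <- norms$slope_raw
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  r2 <- beta^2 * var(x) / var(y)
  expect_equal(out$beta, unname(beta), tolerance = 1e-12)
  expect_equal(out$r2, unname(r2), tolerance = 1e-12)
  expect_equal(out$n, 5)
  # perfectly collinear slopes give R2 = 1
  norms$slope_raw <- 0.001 * tr[norms$taxon]
  expect_equal(flexibility_vs_heterogeneity(norms, tr)$r2, 1)
  # leave-one-out reduces n by exactly 1
  expect_equal(flexibility_vs_heterogeneity(norms, tr, leave_out = "a")$n, 4)
})

test_that("rank-deficient designs raise an informative error", {
  fx <- make_field_fixture()
  ph <- fx$pheno
  ph$taxon[ph$taxon == "mearnsi"][-1] <- "oreganus"
  expect_error(fit_field_model(ph, fx$env, "x", 8), "mearnsi")
})
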