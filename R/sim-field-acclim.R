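#' Generate a field phenotype dataset with planted reaction norms
#'
#' Builds a multi-site field survey: each taxon is sampled at several sites
#' whose weather series differ in mean temperature and daily-range regime;
#' individuals get random capture dates across the year; and summit
#' metabolism follows
#' `M_sum = intercept[taxon] + beta_mass * M_b + slope[taxon] * Tdr + e`,
#' where `Tdr` is the mean daily temperature range over the
#' `window_true`-day window preceding capture (computed from the same
#' weather tables the analysis sees) and `e` is Gaussian with the configured
#' residual sd.  Planted slopes are collinear with the per-taxon annual
#' temperature range, so the downstream flexibility-versus-heterogeneity
#' regression has a known positive slope.
#'
#' @param cfg a [sim_config()]; `cfg$field` holds the parameters.
#' @return list with `pheno` (id, taxon, site, date, season, mass, msum),
#'   `weather` (daily series for all sites), `sites` (site, taxon, lat,
#'   lon, elev, bio7) and `truth` (planted coefficients).
#' @export
gen_field_dataset <- function(cfg) {
  fl <- cfg$field
  if (length(fl$taxa) < 2) stop_tf("need >= 2 taxa")
  with_seed(cfg$seed + 523L, {
    taxa <- fl$taxa
    nt <- length(taxa)
    ns <- fl$n_sites_per_taxon
    sites <- data.frame(
      site = sprintf("%s_s%d", rep(taxa, each = ns), rep(seq_len(ns), nt)),
      taxon = rep(taxa, each = ns),
      lat = runif(nt * ns, 31, 47), lon = runif(nt * ns, -123, -86),
      elev = runif(nt * ns, 200, 2800),
      site_mean = runif(nt * ns, 0, 20),
      dr_mean = runif(nt * ns, 6, 16),
      bio7 = rep(fl$taxon_trange, each = ns) + runif(nt * ns, -1.5, 1.5)
    )
    weather <- do.call(rbind, lapply(seq_len(nrow(sites)), function(i)
      gen_weather(cfg, 365, site = sites$site[i],
                  site_mean = sites$site_mean[i], dr_mean = sites$dr_mean[i],
                  seed_offset = 1000L + i)))
    n <- fl$n_per_taxon
    taxon <- rep(taxa, each = n)
    site <- unlist(lapply(taxa, function(tx)
      sample(sites$site[sites$taxon == tx], n, replace = TRUE)))
    date <- as.Date("2018-01-01") + sample(29:359, nt * n, replace = TRUE)
    doy <- as.integer(format(date, "%j"))
    season <- ifelse(doy >= 121 & doy <= 212, "breeding", "nonbreeding")
    mass <- rnorm(nt * n, fl$mass_mean, fl$mass_sd)
    k <- fl$window_true
    tdr_true <- vapply(seq_len(nt * n), function(i) {
      w <- weather[weather$site == site[i] &
                     weather$date >= date[i] - k & weather$date <= date[i] - 1, ]
      mean(w$tmax - w$tmin)
    }, numeric(1))
    idx <- match(taxon, taxa)
    msum <- fl$intercepts[idx] + fl$beta_mass * mass +
      fl$slopes[idx] * tdr_true + rnorm(nt * n, 0, fl$resid_sd)
    pheno <- data.frame(
      id = sprintf("F%04d", seq_len(nt * n)), taxon = taxon, site = site,
      date = date, season = season, mass = mass, msum = msum
    )
    list(pheno = pheno, weather = weather,
         sites = sites[, c("site", "taxon", "lat", "lon", "elev", "bio7")],
         truth = list(slopes = setNames(fl$slopes, taxa),
                      intercepts = setNames(fl$intercepts, taxa),
                      beta_mass = fl$beta_mass, window_true = k,
                      taxon_trange = setNames(fl$taxon_trange, taxa),
                      tdr_true = tdr_true))
  })
}

#' Generate an acclimation-experiment dataset with a planted interaction
#'
#' Emulates the common-garden design: individuals from populations differing
#' in native annual temperature range (`T_range`), randomized to cold or
#' control treatment, with pre/post body mass and summit metabolism.  The
#' change in summit metabolism follows
#' `dMsum = b0 + b_mb*z(Mb) + b_t*cold + b_int*cold*z(Trange) + u_pop + e`
#' with all continuous covariates standardized by two standard deviations,
#' `u_pop` Gaussian with the covariance implied by the supplied F_ST matrix
#' (similarity `1 - theta`), and the residual sd of cold birds decreasing in
#' `T_range`, planting the expectation that more variable climates show
#' smaller coefficients of variation in flexibility.
#'
#' @param cfg a [sim_config()]; `cfg$acclimation` holds the parameters.
#' @param fst optional population-by-population Weir's theta matrix
#'   (dimnames = population names); a plausible matrix in the 0.019-0.051
#'   range is generated when omitted.  A missing (NA) pair is an error.
#' @return list with `records` (an acclimation table), `fst`, and `truth`.
#' @export
gen_acclimation_dataset <- function(cfg, fst = NULL) {
  ac <- cfg$acclimation
  pops <- ac$pops
  k <- length(pops)
  if (k < 2) stop_tf("need >= 2 populations")
  with_seed(cfg$seed + 631L, {
    if (is.null(fst)) {
      th <- matrix(0, k, k, dimnames = list(pops, pops))
      th[upper.tri(th)] <- runif(k * (k - 1) / 2, 0.019, 0.051)
      th <- th + t(th)
    } else {
      th <- if (inherits(fst, "fst_matrix")) fst$theta else as.matrix(fst)
      th <- th[pops, pops]
    }
    if (any(is.na(th[upper.tri(th)])))
      stop_tf("F_ST missing for at least one population pair")
    n <- ac$n_per_pop_per_trt
    population <- factor(rep(pops, each = 2 * n), levels = pops)
    treatment <- rep(rep(c("control", "cold"), each = n), k)
    trange <- rep(ac$trange, each = 2 * n)
    z2 <- function(x) (x - mean(x)) / (2 * sd(x))
    z_tr <- z2(trange)
    pre_mb <- ac$mass_mean + ac$mass_trange_beta * z_tr +
      rnorm(2 * n * k, 0, ac$mass_sd)
    z_mb <- z2(pre_mb)
    pre_msum <- ac$msum_base + ac$msum_trange_beta * z_tr +
      ac$msum_mass_beta * (pre_mb - ac$mass_mean) +
      rnorm(2 * n * k, 0, ac$msum_sd)
    S <- fst_covariance(th)$S
    u <- ac$sd_u * drop(crossprod(chol(S + 1e-8 * diag(k)), rnorm(k)))
    cold <- as.numeric(treatment == "cold")
    sd_e <- ifelse(cold == 1,
                   ac$resid_sd_cold_base * exp(ac$resid_log_sd_slope * z_tr),
                   ac$resid_sd_control)
    delta <- ac$beta0 + ac$beta_mb * z_mb + ac$beta_treat * cold +
      ac$beta_int * cold * z_tr + u[as.integer(population)] +
      rnorm(2 * n * k, 0, sd_e)
    season <- ifelse(population == "aikeni", "nonbreeding", "breeding")
    records <- data.frame(
      id = sprintf("A%03d", seq_len(2 * n * k)),
      population = population, treatment = treatment, season = season,
      pre_mb = pre_mb, post_mb = pre_mb + rnorm(2 * n * k, 0, 0.4),
      pre_msum = pre_msum, post_msum = pre_msum + delta,
      trange = trange
    )
    list(records = records, fst = th,
         truth = list(beta0 = ac$beta0, beta_mb = ac$beta_mb,
                      beta_treat = ac$beta_treat, beta_int = ac$beta_int,
                      u = setNames(u, pops), sd_u = ac$sd_u,
                      resid_log_sd_slope = ac$resid_log_sd_slope))
  })
}
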