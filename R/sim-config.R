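#' Simulation configuration for the synthetic-data generators
#'
#' Bundles every tunable of the synthetic-data module into one validated
#' object.  The defaults encode the study conditions the downstream analyses
#' assume: a respirometry trace with a known summit metabolic rate plus
#' baseline drift and instrument noise; daily weather with a seasonal cycle;
#' genotypes under a Balding-Nichols island model with an environmental cline
#' planted at a subset of loci; field M_sum with taxon-specific reaction-norm
#' slopes on daily temperature range; and an acclimation experiment with a
#' planted treatment-by-T_range interaction and T_range-dependent residual
#' spread in the cold group.
#'
#' Components (all overridable by passing a named list that is merged over
#' the defaults):
#' \describe{
#'   \item{trace}{`true_msum` (ml O2 min^-1), `fio2`, `flow` (ml min^-1),
#'     `duration_s`, `baseline_s`, `ramp_s`, `plateau_s`, `rest_vo2`,
#'     `drift_pct_per_hr` (%O2 per hour added linearly over the run),
#'     `noise_sd` (O2 fraction).}
#'   \item{weather}{`site_mean` (degC), `seasonal_amp` (degC),
#'     `dr_mean` daily-range mean (degC), `dr_seasonal_amp`, `dr_sd`,
#'     `noise_sd` (midpoint jitter, degC).}
#'   \item{field}{taxa, sites per taxon, per-taxon intercepts and raw
#'     reaction-norm slopes (ml O2 min^-1 degC^-1) on the `window_true`-day
#'     mean daily temperature range, per-taxon annual temperature range
#'     (degC), body-mass distribution and effect, residual sd.}
#'   \item{genotype}{`n_pops`, `n_per_pop`, `n_loci`, `fst` target,
#'     `n_adaptive` loci, `env_effect` (logit allele-frequency shift per SD
#'     of the planted site variable), depth and missingness models.}
#'   \item{acclimation}{population names, native annual temperature ranges
#'     (degC, BIO7), group sizes, standardized fixed effects (per 2 SD),
#'     population random-effect sd, and the residual-sd model for cold birds
#'     (`resid_sd_cold_base * exp(resid_log_sd_slope * z)` with `z` the
#'     2-SD-standardized T_range).}
#' }
#'
#' @param seed integer master seed; fixing it makes every generator output
#'   byte-identical across runs.
#' @param ... named lists (`trace`, `weather`, `field`, `genotype`,
#'   `acclimation`) whose elements override the defaults.
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1, trace = list(true_msum = 8))
#' cfg$trace$true_msum
#' @export
sim_config <- function(seed = 1L, ...) {
  defaults <- list(
    trace = list(
      true_msum = 7, fio2 = 0.2095, flow = 500,
      duration_s = 3600, baseline_s = 300, ramp_s = 600, plateau_s = 600,
      rest_vo2 = 1.0, drift_pct_per_hr = 0.05, noise_sd = 5e-4
    ),
    weather = list(
      site_mean = 8, seasonal_amp = 12,
      dr_mean = 10, dr_seasonal_amp = 3, dr_sd = 4.5, noise_sd = 2
    ),
    field = list(
      taxa = c("caniceps", "hyemalis", "mearnsi", "oreganus", "palliatus"),
      taxon_trange = c(37, 43, 25, 31, 49),
      slopes = 0.10 + 0.007 * (c(37, 43, 25, 31, 49) - 25),
      intercepts = c(-4.2, -2.8, -4.8, -4.0, -5.2),
      n_per_taxon = 100, n_sites_per_taxon = 4,
      mass_mean = 19, mass_sd = 1.2, beta_mass = 0.5,
      resid_sd = 0.8, window_true = 8
    ),
    genotype = list(
      n_pops = 5, n_per_pop = 20, n_loci = 2000,
      fst = 0.05, n_lineages = 3, lineage_fst_frac = 0.6,
      n_adaptive = 100, env_effect = 0.8,
      anc_freq_range = c(0.1, 0.9),
      depth_mean = 20, depth_sdlog = 0.35, missing_rate = 0.02
    ),
    acclimation = list(
      pops = c("aikeni", "dorsalis", "palliatus", "shufeldti", "thurberi"),
      trange = c(45, 39, 33, 26, 24),
      n_per_pop_per_trt = 10,
      beta0 = 0.05, beta_mb = 0.53, beta_treat = 0.62, beta_int = 0.60,
      sd_u = 0.10,
      resid_sd_control = 0.30, resid_sd_cold_base = 0.30,
      resid_log_sd_slope = -0.8,
      mass_mean = 19, mass_sd = 1.2, mass_trange_beta = 0,
      msum_base = 7.5, msum_trange_beta = 1.1, msum_mass_beta = 0.16,
      msum_sd = 0.5
    )
  )
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) stop_tf("unknown sim_config component(s): %s",
                           paste(bad, collapse = ", "))
  for (nm in names(over)) {
    stopifnot(is.list(over[[nm]]))
    bad2 <- setdiff(names(over[[nm]]), names(defaults[[nm]]))
    if (length(bad2)) stop_tf("unknown %s parameter(s): %s", nm,
                              paste(bad2, collapse = ", "))
    defaults[[nm]][names(over[[nm]])] <- over[[nm]]
  }
  cfg <- c(list(seed = as.integer(seed)), defaults)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  tr <- cfg$trace
  if (tr$true_msum <= 0) stop_tf("trace$true_msum must be > 0")
  if (tr$flow <= 0) stop_tf("trace$flow must be > 0")
  if (tr$duration_s <= 0 || tr$baseline_s <= 0)
    stop_tf("trace durations must be positive")
  g <- cfg$genotype
  if (g$fst <= 0 || g$fst >= 1) stop_tf("genotype$fst must lie in (0, 1)")
  if (g$n_adaptive > g$n_loci)
    stop_tf("genotype$n_adaptive (%d) exceeds n_loci (%d)",
            g$n_adaptive, g$n_loci)
  fl <- cfg$field
  k <- length(fl$taxa)
  if (length(fl$slopes) != k || length(fl$intercepts) != k ||
      length(fl$taxon_trange) != k)
    stop_tf("field taxa, slopes, intercepts and taxon_trange must align")
  ac <- cfg$acclimation
  if (length(ac$trange) != length(ac$pops))
    stop_tf("acclimation pops and trange must align")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> seed =", x$seed, "\n")
  cat("  trace:  true M_sum", x$trace$true_msum, "ml O2/min, flow",
      x$trace$flow, "ml/min, noise sd", x$trace$noise_sd, "\n")
  cat("  field: ", length(x$field$taxa), "taxa x", x$field$n_per_taxon,
      "inds, slopes", paste(round(x$field$slopes, 3), collapse = "/"), "\n")
  cat("  genotype:", x$genotype$n_pops, "pops x", x$genotype$n_per_pop,
      "inds x", x$genotype$n_loci, "loci, F_ST target", x$genotype$fst, "\n")
  cat("  acclimation:", length(x$acclimation$pops), "pops, beta_int",
      x$acclimation$beta_int, "\n")
  invisible(x)
}
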