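#' Generate a synthetic respirometry trace with known summit metabolism
#'
#' Emulates an open-flow heliox trial at 1 Hz: a pre-animal baseline, an
#' animal segment whose underlying VO2 ramps from resting to a plateau at
#' the planted `true_msum` (held longer than the averaging window, so the
#' drift-free 5-min maximum equals the planted value exactly), a decline,
#' and a post-animal baseline.  A linear baseline drift (`drift_pct_per_hr`)
#' and Gaussian sensor noise (`noise_sd`, O2 fraction) are superimposed; the
#' excurrent fraction is derived by inverting the downstream-flow VO2
#' equation against the drifting reference, so drift correction plus the
#' steady-state equation recover the planted value.
#'
#' @param cfg a [sim_config()]; `cfg$trace` holds the parameters.
#' @param seed_offset internal stream offset so multiple traces from one
#'   config differ while remaining reproducible.
#' @return A [resp_trace()] with attribute `true_msum`.
#' @export
gen_resp_trace <- function(cfg, seed_offset = 0L) {
  tr <- cfg$trace
  with_seed(cfg$seed + 101L + seed_offset, {
    dt <- 1
    n_base <- as.integer(tr$baseline_s / dt)
    n_anim <- as.integer(tr$duration_s / dt)
    n <- 2L * n_base + n_anim
    time_s <- seq(0, by = dt, length.out = n)
    drift_per_s <- tr$drift_pct_per_hr / 100 / 3600
    ref <- tr$fio2 + drift_per_s * time_s

    # underlying VO2 profile over the animal segment
    t_anim <- seq(0, by = dt, length.out = n_anim)
    ramp_n <- as.integer(tr$ramp_s / dt)
    plat_n <- as.integer(tr$plateau_s / dt)
    vo2 <- numeric(n_anim)
    vo2[seq_len(ramp_n)] <-
      tr$rest_vo2 + (tr$true_msum - tr$rest_vo2) * seq_len(ramp_n) / ramp_n
    vo2[ramp_n + seq_len(plat_n)] <- tr$true_msum
    rest_n <- n_anim - ramp_n - plat_n
    if (rest_n > 0)
      vo2[ramp_n + plat_n + seq_len(rest_n)] <-
        tr$true_msum - (tr$true_msum - tr$rest_vo2) * seq_len(rest_n) / rest_n

    feo2 <- ref
    anim <- n_base + seq_len(n_anim)
    feo2[anim] <- ref[anim] - vo2 * (1 - ref[anim]) / tr$flow
    feo2 <- feo2 + rnorm(n, 0, tr$noise_sd)
    baselines <- data.frame(
      start = c(1L, n_base + n_anim + 1L),
      end = c(n_base, n),
      phase = c("pre", "post")
    )
    out <- resp_trace(time_s, feo2, tr$flow, fio2 = tr$fio2,
                      baselines = baselines)
    attr(out, "true_msum") <- tr$true_msum
    out
  })
}

#' Generate a DayMet-style daily weather series
#'
#' Daily minimum and maximum temperature follow a seasonal sinusoid of the
#' configured amplitude around the site mean, split by a daily temperature
#' range whose mean, seasonal modulation and day-to-day spread are
#' configured; precipitation, vapor pressure, shortwave radiation and
#' daylength are filled with plausible covarying values so every DayMet
#' field the downstream window builder consumes is populated.  With all
#' amplitude and noise parameters zero, `tmax - tmin` is constant and equal
#' to the configured daily-range mean.
#'
#' @param cfg a [sim_config()]; `cfg$weather` holds the parameters.
#' @param n_days number of days (>= 14).
#' @param site site identifier written into the `site` column.
#' @param start_date first date of the series.
#' @param site_mean,dr_mean optional per-site overrides of the configured
#'   site mean temperature and daily-range mean.
#' @param seed_offset internal stream offset for multi-site generation.
#' @return data.frame `site, date, tmin, tmax, prcp, vp, srad, dayl`.
#' @export
gen_weather <- function(cfg, n_days, site = "S1",
                        start_date = as.Date("2018-01-01"),
                        site_mean = NULL, dr_mean = NULL,
                        seed_offset = 0L) {
  if (n_days < 14) stop_tf("n_days must be >= 14")
  w <- cfg$weather
  site_mean <- site_mean %||% w$site_mean
  dr_mean <- dr_mean %||% w$dr_mean
  with_seed(cfg$seed + 211L + seed_offset, {
    date <- start_date + seq_len(n_days) - 1L
    doy <- as.integer(format(date, "%j"))
    mid <- site_mean + w$seasonal_amp * cos(2 * pi * (doy - 196) / 365) +
      rnorm(n_days, 0, w$noise_sd)
    dr <- dr_mean + w$dr_seasonal_amp * cos(2 * pi * (doy - 15) / 365) +
      rnorm(n_days, 0, w$dr_sd)
    dr <- pmax(dr, 0.5 * (dr_mean > 0))
    tmin <- mid - dr / 2
    tmax <- mid + dr / 2
    wet <- rbinom(n_days, 1, 0.3)
    prcp <- wet * rexp(n_days, 1 / 5)
    vp <- 610.8 * exp(17.27 * tmin / (tmin + 237.3))  # saturation vp at tmin
    srad <- pmax(50, 250 + 120 * cos(2 * pi * (doy - 172) / 365) +
                   rnorm(n_days, 0, 20))
    dayl <- 43200 + 12000 * cos(2 * pi * (doy - 172) / 365)
    data.frame(site = site, date = date, tmin = tmin, tmax = tmax,
               prcp = prcp, vp = vp, srad = srad, dayl = dayl)
  })
}
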