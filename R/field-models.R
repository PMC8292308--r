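#' Fit one field M_sum model
#'
#' Ordinary least squares for `M_sum = M_b + taxon * variable`: body mass
#' and the environmental variable are standardized by two standard
#' deviations on the complete-case analysis subset, the taxon enters as a
#' factor with a configurable reference level, and the interaction encodes
#' taxon-specific reaction norms.  AIC is the usual Gaussian value
#' (constant included, residual variance counted as a parameter), so model
#' ranks are comparable across candidates fitted to the same rows.
#'
#' @param pheno data.frame with `id`, `taxon`, `msum`, `mass`.
#' @param env per-individual feature table from [build_env_features()].
#' @param variable feature column to use as the environmental predictor.
#' @param window window length (days) to select from `env`; `NA` for
#'   window-free variables such as elevation (any row of `env` carries
#'   them, the first per id is used).
#' @param ref_taxon reference taxon for reported coefficients (defaults to
#'   `"oreganus"` when present, the widespread western group).
#' @return A `field_model` list: the `lm` fit, `aic`, `r2`, `n`, the raw-sd
#'   of the variable (for back-transforming slopes), and the analysis data.
#' @export
fit_field_model <- function(pheno, env, variable, window = NA,
                            ref_taxon = NULL) {
  ev <- if (is.na(window)) env[!duplicated(env$id), ]
        else env[env$window == window, ]
  if (!variable %in% names(ev)) stop_tf("variable '%s' not in features", variable)
  d <- merge(pheno[, c("id", "taxon", "msum", "mass",
                       intersect("season", names(pheno)))],
             ev[, c("id", variable)], by = "id")
  names(d)[names(d) == variable] <- "env_raw"
  d <- d[complete.cases(d[, c("msum", "mass", "taxon", "env_raw")]), ]
  d$taxon <- droplevels(factor(d$taxon))
  if (nlevels(d$taxon) < 2) stop_tf("need >= 2 taxa with data")
  ref_taxon <- ref_taxon %||%
    (if ("oreganus" %in% levels(d$taxon)) "oreganus" else levels(d$taxon)[1])
  d$taxon <- relevel(d$taxon, ref = ref_taxon)
  bad <- tapply(d$env_raw, d$taxon, function(x) length(x) < 2 || sd(x) == 0)
  if (any(bad))
    stop_tf("taxa with < 2 observations spanning %s: %s", variable,
            paste(names(bad)[bad], collapse = ", "))
  d$mb_std <- standardize_2sd(d$mass)
  d$env_std <- standardize_2sd(d$env_raw)
  fit <- lm(msum ~ mb_std + taxon * env_std, data = d)
  out <- list(fit = fit, variable = variable, window = window,
              aic = AIC(fit), r2 = summary(fit)$r.squared, n = nrow(d),
              sd_raw = attr(d$env_std, "scale_sd"),
              sd_mb_raw = attr(d$mb_std, "scale_sd"),
              ref_taxon = ref_taxon, data = d)
  class(out) <- "field_model"
  out
}

#' @export
print.field_model <- function(x, ...) {
  cat("<field_model>", x$variable,
      if (!is.na(x$window)) sprintf("(%d-day window)", x$window) else "",
      " AIC =", round(x$aic, 1), " R2 =", round(x$r2, 3), " n =", x$n, "\n")
  invisible(x)
}

#' Rank environmental variable x window candidates by AIC
#'
#' Fits `M_sum = M_b + taxon * variable` for every combination of weather
#' variable and acclimatization window (plus window-free variables and the
#' null model `M_sum = M_b + taxon`), ranks them by AIC, and reports, for
#' the best candidate, the AIC cost of dropping the taxon interaction and
#' of adding a season term.
#'
#' @inheritParams fit_field_model
#' @param variables weather variables to screen.
#' @param windows window lengths (days) to screen.
#' @param window_free variables carried per site rather than per window.
#' @return list with `ranking` (data.frame ordered by AIC, including the
#'   null row), `best` (the winning `field_model`),
#'   `delta_aic_interaction` (AIC without minus with the interaction;
#'   positive means the interaction improves fit) and `delta_aic_season`
#'   (AIC with season minus best, when a season column exists).
#' @export
select_model <- function(pheno, env,
                         variables = c("tmin", "tmax", "prcp", "dayl", "vp",
                                       "srad", "t_d_range"),
                         windows = 7:14, window_free = "elev",
                         ref_taxon = NULL) {
  cand <- rbind(
    expand.grid(variable = variables, window = windows,
                stringsAsFactors = FALSE),
    data.frame(variable = intersect(window_free, names(env)), window = NA)
  )
  fits <- lapply(seq_len(nrow(cand)), function(i)
    fit_field_model(pheno, env, cand$variable[i], cand$window[i],
                    ref_taxon = ref_taxon))
  ranking <- data.frame(
    variable = cand$variable, window = cand$window,
    aic = vapply(fits, `[[`, numeric(1), "aic"),
    r2 = vapply(fits, `[[`, numeric(1), "r2"),
    n = vapply(fits, `[[`, numeric(1), "n")
  )
  # null model: M_b + taxon only, on the same standardization logic
  d0 <- fits[[1]]$data
  null_fit <- lm(msum ~ mb_std + taxon, data = d0)
  ranking <- rbind(ranking,
                   data.frame(variable = "null", window = NA,
                              aic = AIC(null_fit),
                              r2 = summary(null_fit)$r.squared, n = nrow(d0)))
  ranking <- ranking[order(ranking$aic), ]
  ranking$delta_aic <- ranking$aic - ranking$aic[1]
  rownames(ranking) <- NULL
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "aic"))]]
  no_int <- lm(msum ~ mb_std + taxon + env_std, data = best$data)
  delta_int <- AIC(no_int) - best$aic
  delta_season <- NA_real_
  if ("season" %in% names(best$data) &&
      length(unique(best$data$season)) > 1) {
    with_season <- lm(msum ~ mb_std + taxon * env_std + season,
                      data = best$data)
    delta_season <- AIC(with_season) - best$aic
  }
  list(ranking = ranking, best = best,
       delta_aic_interaction = delta_int,
       delta_aic_season = delta_season)
}

#' Raw-scale taxon reaction norms from the best field model
#'
#' The fitted model is on the 2-SD standardized scale; each taxon's raw
#' reaction norm (ml O2 min^-1 degC^-1) is the reference-taxon slope plus
#' that taxon's interaction coefficient, divided by twice the raw standard
#' deviation of the variable.  Standard errors propagate through the
#' coefficient covariance.
#'
#' @param fm a `field_model` containing the taxon x variable interaction.
#' @return data.frame `taxon`, `slope_std`, `slope_raw`, `se_raw`, `lo95`,
#'   `hi95` (95% confidence bounds on the raw scale).
#' @export
reaction_norm_slopes <- function(fm) {
  cf <- coef(fm$fit)
  V <- vcov(fm$fit)
  if (!"env_std" %in% names(cf))
    stop_tf("model has no environmental slope term")
  int_terms <- grep(":env_std$", names(cf), value = TRUE)
  if (!length(int_terms)) stop_tf("model has no taxon x variable interaction")
  taxa <- levels(fm$data$taxon)
  dfres <- fm$fit$df.residual
  rows <- lapply(taxa, function(tx) {
    term <- paste0("taxon", tx, ":env_std")
    if (tx == fm$ref_taxon) {
      est <- cf[["env_std"]]
      se <- sqrt(V["env_std", "env_std"])
    } else {
      est <- cf[["env_std"]] + cf[[term]]
      se <- sqrt(V["env_std", "env_std"] + V[term, term] +
                   2 * V["env_std", term])
    }
    raw <- est / (2 * fm$sd_raw)
    se_raw <- se / (2 * fm$sd_raw)
    q <- qt(0.975, dfres)
    data.frame(taxon = tx, slope_std = est, slope_raw = raw, se_raw = se_raw,
               lo95 = raw - q * se_raw, hi95 = raw + q * se_raw)
  })
  do.call(rbind, rows)
}

#' Mean annual temperature range per taxon
#'
#' Unweighted mean of BIO7 over each taxon's individuals' capture sites;
#' note the weighting unit is the individual, not the unique site.
#'
#' @param pheno data.frame with `taxon` and `site`.
#' @param sites site table with `site` and `bio7`.
#' @return named numeric vector, degC.
#' @export
taxon_mean_trange <- function(pheno, sites) {
  b <- sites$bio7[match(pheno$site, sites$site)]
  tapply(b, pheno$taxon, mean)
}

#' Regress flexibility magnitude on thermal heterogeneity
#'
#' Simple linear regression of the taxon reaction-norm slopes on the mean
#' annual temperature range per taxon, optionally excluding one taxon.
#'
#' @param norms output of [reaction_norm_slopes()].
#' @param trange named vector (names = taxa) of mean annual temperature
#'   range, degC.
#' @param leave_out optional taxon name to exclude.
#' @return list `r2`, `beta` (slope per degC), `se`, `p` (two-sided), `n`,
#'   and the `lm` fit.
#' @export
flexibility_vs_heterogeneity <- function(norms, trange, leave_out = NULL) {
  d <- data.frame(taxon = norms$taxon, slope = norms$slope_raw,
                  trange = as.numeric(trange[norms$taxon]))
  if (!is.null(leave_out)) d <- d[d$taxon != leave_out, ]
  if (nrow(d) < 3) stop_tf("need n >= 3 taxa after exclusion")
  fit <- lm(slope ~ trange, data = d)
  sm <- summary(fit)
  list(r2 = sm$r.squared, beta = coef(fit)[["trange"]],
       se = sm$coefficients["trange", "Std. Error"],
       p = sm$coefficients["trange", "Pr(>|t|)"], n = nrow(d), fit = fit)
}
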