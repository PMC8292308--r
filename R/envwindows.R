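#' Daily temperature range
#'
#' Elementwise `tmax - tmin` for a daily weather table.
#'
#' @param ws data.frame with `tmin` and `tmax` columns (degC).
#' @return numeric vector, degC.
#' @export
daily_range <- function(ws) {
  if (any(ws$tmax < ws$tmin)) stop_tf("tmax < tmin in weather table")
  ws$tmax - ws$tmin
}

#' Acclimatization-window mean of a weather variable
#'
#' Arithmetic mean over the `k` days strictly preceding the capture date
#' (days capture-1 ... capture-k; the capture day itself is excluded).  Any
#' missing day is an error naming the gap -- no silent imputation.
#'
#' @param ws weather data.frame (`site`, `date`, plus variable columns;
#'   `t_d_range` is accepted and computed on the fly).
#' @param site site identifier to subset on.
#' @param capture_date a `Date`.
#' @param k window length in days (the study screens 7 to 14).
#' @param variable column name, or `"t_d_range"` for `tmax - tmin`.
#' @return scalar mean.
#' @export
window_mean <- function(ws, site, capture_date, k, variable) {
  capture_date <- as.Date(capture_date)
  want <- capture_date - seq_len(k)
  w <- ws[ws$site == site, ]
  hit <- match(want, as.Date(w$date))
  if (anyNA(hit))
    stop_tf("site %s is missing weather for: %s", site,
            paste(format(want[is.na(hit)]), collapse = ", "))
  x <- if (identical(variable, "t_d_range")) daily_range(w[hit, ])
       else w[[variable]][hit]
  mean(x)
}

#' Standardize by two standard deviations
#'
#' Centers and divides by twice the sample standard deviation (n-1
#' denominator), putting continuous predictors on a scale comparable with
#' binary ones; the result has mean 0 and sd 0.5.
#'
#' @param x numeric vector, `n >= 2`, non-constant.
#' @return standardized vector with attributes `center` and `scale_sd`
#'   (the raw sd, useful for back-transforming coefficients).
#' @export
standardize_2sd <- function(x) {
  if (length(x) < 2) stop_tf("need n >= 2 to standardize")
  s <- sd(x)
  if (!is.finite(s) || s == 0) stop_tf("cannot 2-SD-standardize a constant vector")
  out <- (x - mean(x)) / (2 * s)
  attr(out, "center") <- mean(x)
  attr(out, "scale_sd") <- s
  out
}

#' Per-individual environmental features across acclimatization windows
#'
#' For each individual and each window length `k`, computes the window mean
#' of every daily weather variable (plus daily temperature range) over the
#' `k` days preceding capture, and joins the window-free site covariates
#' (elevation, annual temperature range BIO7) when a site table is given.
#'
#' @param pheno data.frame with `id`, `site`, `date`.
#' @param weather daily weather table covering every needed site-day.
#' @param windows integer vector of window lengths (days), default 7:14.
#' @param sites optional site table with `site` and any of `elev`, `bio7`.
#' @param variables weather variables to average.
#' @return data.frame with one row per individual x window.
#' @export
build_env_features <- function(pheno, weather, windows = 7:14, sites = NULL,
                               variables = c("tmin", "tmax", "prcp", "vp",
                                             "srad", "dayl", "t_d_range")) {
  by_site <- split(weather, weather$site)
  grid <- expand.grid(row = seq_len(nrow(pheno)), window = windows)
  out <- data.frame(id = pheno$id[grid$row], window = grid$window)
  vals <- matrix(NA_real_, nrow(grid), length(variables),
                 dimnames = list(NULL, variables))
  for (j in seq_len(nrow(grid))) {
    i <- grid$row[j]
    k <- grid$window[j]
    w <- by_site[[as.character(pheno$site[i])]]
    if (is.null(w)) stop_tf("no weather for site %s", pheno$site[i])
    want <- as.Date(pheno$date[i]) - seq_len(k)
    hit <- match(want, as.Date(w$date))
    if (anyNA(hit))
      stop_tf("site %s is missing weather for: %s", pheno$site[i],
              paste(format(want[is.na(hit)]), collapse = ", "))
    for (v in variables)
      vals[j, v] <- if (identical(v, "t_d_range"))
        mean(daily_range(w[hit, ])) else mean(w[[v]][hit])
  }
  for (v in variables) out[[v]] <- vals[, v]
  if (!is.null(sites)) {
    m <- match(pheno$site[grid$row], sites$site)
    for (v in intersect(c("elev", "bio7"), names(sites)))
      out[[v]] <- sites[[v]][m]
  }
  out
}
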