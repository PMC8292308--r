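#' Population covariance structure from pairwise F_ST
#'
#' Interprets pairwise differentiation as declining similarity: the
#' population-level matrix has unit diagonal and off-diagonal entries
#' `1 - theta_ij`, projected to the nearest positive semidefinite matrix by
#' eigenvalue clipping at zero with the diagonal renormalized to one.  An
#' alternative construction passes the linearized F_ST distance through a
#' Gaussian kernel `exp(-d / lambda)`.  When an individual-to-population
#' map is supplied the structure is expanded to individuals by membership.
#'
#' @param f an `fst_matrix` or plain symmetric theta matrix (dimnames =
#'   populations); any `NA` pair is an error.
#' @param pops optional factor/character of population membership per
#'   individual; enables the expanded matrix.
#' @param mode `"similarity"` (1 - theta) or `"kernel"`
#'   (`exp(-linearized/lambda)`).
#' @param lambda kernel bandwidth for `mode = "kernel"`.
#' @return list `S` (population-level matrix), `S_ind` (individual-level,
#'   when `pops` given), `min_eig` (smallest eigenvalue before clipping).
#' @export
fst_covariance <- function(f, pops = NULL,
                           mode = c("similarity", "kernel"), lambda = 0.05) {
  mode <- match.arg(mode)
  th <- if (inherits(f, "fst_matrix")) f$theta else as.matrix(f)
  if (any(is.na(th))) stop_tf("F_ST missing for at least one population pair")
  S <- switch(mode,
              similarity = { s <- 1 - th; diag(s) <- 1; s },
              kernel = { d <- th / (1 - th); diag(d) <- 0; exp(-d / lambda) })
  ev <- eigen(S, symmetric = TRUE)
  min_eig <- min(ev$values)
  if (min_eig < 0) {
    vals <- pmax(ev$values, 0)
    S <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
    dsc <- sqrt(pmax(diag(S), .Machine$double.eps))
    S <- S / tcrossprod(dsc)
    dimnames(S) <- dimnames(th)
  }
  out <- list(S = S, min_eig = min_eig)
  if (!is.null(pops)) {
    pops <- as.character(pops)
    if (!all(pops %in% rownames(S)))
      stop_tf("populations missing from F_ST matrix: %s",
              paste(setdiff(unique(pops), rownames(S)), collapse = ", "))
    out$S_ind <- S[pops, pops]
  }
  out
}

ess_one <- function(x) {
  n <- length(x)
  if (n < 10 || sd(x) == 0) return(n)
  rho <- acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  pos <- which(rho < 0.05)
  cut <- if (length(pos)) pos[1] - 1 else length(rho)
  denom <- 1 + 2 * sum(rho[seq_len(cut)])
  min(n, n / max(denom, 1e-8))
}

#' Gibbs sampler for a Gaussian linear mixed model with structured
#' random effect
#'
#' Samples from `y = X b + Z u + e`, `u ~ N(0, s2_u * S)`,
#' `e ~ N(0, s2_e * I)` with conjugate updates: a joint multivariate-normal
#' block draw for `(b, u)` and inverse-gamma draws for the two variances.
#' Priors are weakly informative and configurable: `N(0, v_fixed)` on
#' fixed effects and `IG(shape, scale)` on variances.  `pMCMC` is twice
#' the smaller posterior tail probability of an effect crossing zero,
#' floored at `1 / n_samples`; an effective sample size computed from the
#' autocorrelation of each chain is reported as a convergence check.
#' Degenerate variance draws are capped (with a counter) rather than
#' allowed to diverge.
#'
#' @param y numeric response.
#' @param X fixed-effect design matrix (include the intercept column).
#' @param Z random-effect incidence matrix (individuals x levels), or
#'   `NULL` for a fixed-effects-only model.
#' @param S random-effect covariance structure (levels x levels, PSD; see
#'   [fst_covariance()]).
#' @param n_iter,burn_in,thin MCMC schedule.  The default schedule
#'   (1e6 / 1e4 / 100) mirrors the analysis configuration; 1e5 iterations
#'   give near-identical summaries in a few seconds and are used
#'   throughout the tests.
#' @param seed optional seed pinning the chain.
#' @param priors list with `v_fixed`, `ig_shape`, `ig_scale`.
#' @param fix_sigma2_u optional fixed value for the random-effect variance
#'   (0 collapses the model to Bayesian linear regression).
#' @return A `posterior_summary`: `fixed` (data.frame with posterior mean,
#'   95% credible interval, pMCMC and effective sample size per
#'   coefficient), `sigma2_u`, `sigma2_e` summaries, `n_samples`,
#'   `n_capped`, and the retained `samples` matrix.
#' @export
gibbs_lmm <- function(y, X, Z = NULL, S = NULL,
                      n_iter = 1e6, burn_in = 1e4, thin = 100, seed = NULL,
                      priors = list(v_fixed = 1e8, ig_shape = 0.001,
                                    ig_scale = 0.001),
                      fix_sigma2_u = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- length(y)
  p <- ncol(X)
  has_u <- !is.null(Z) && is.null(fix_sigma2_u)
  if (!is.null(fix_sigma2_u) && fix_sigma2_u == 0) Z <- NULL
  q <- if (!is.null(Z)) ncol(Z) else 0L
  W <- if (q > 0) cbind(X, as.matrix(Z)) else X
  WtW <- crossprod(W)
  Wty <- crossprod(W, y)
  if (q > 0) {
    if (is.null(S)) S <- diag(q)
    es <- eigen(S, symmetric = TRUE)
    vals <- pmax(es$values, max(es$values) * 1e-8)
    Sinv <- es$vectors %*% diag(1 / vals) %*% t(es$vectors)
  }
  pri_v <- priors$v_fixed %||% 1e8
  a0 <- priors$ig_shape %||% 0.001
  b0 <- priors$ig_scale %||% 0.001
  keep_at <- seq(burn_in + thin, n_iter, by = thin)
  samples <- matrix(NA_real_, length(keep_at), p + q + 2)
  colnames(samples) <- c(colnames(X) %||% paste0("b", seq_len(p)),
                         if (q > 0) paste0("u_", colnames(Z) %||% seq_len(q)),
                         "sigma2_u", "sigma2_e")
  cap <- max(var(y), 1) * 1e6
  run <- function() {
    sig_e <- max(var(y), 1e-6)
    sig_u <- if (has_u) sig_e / 2 else (fix_sigma2_u %||% 0)
    n_capped <- 0L
    ki <- 1L
    idx_u <- if (q > 0) p + seq_len(q) else integer(0)
    for (it in seq_len(n_iter)) {
      P <- WtW / sig_e
      diag(P)[seq_len(p)] <- diag(P)[seq_len(p)] + 1 / pri_v
      if (q > 0) P[idx_u, idx_u] <- P[idx_u, idx_u] + Sinv / max(sig_u, 1e-12)
      U <- chol(P)
      mu <- backsolve(U, forwardsolve(t(U), Wty / sig_e))
      theta <- mu + backsolve(U, rnorm(p + q))
      res <- y - W %*% theta
      sig_e <- 1 / rgamma(1, a0 + n / 2, b0 + sum(res^2) / 2)
      if (sig_e > cap) { sig_e <- cap; n_capped <- n_capped + 1L }
      if (has_u) {
        u <- theta[idx_u]
        sig_u <- 1 / rgamma(1, a0 + q / 2,
                            b0 + sum(u * (Sinv %*% u)) / 2)
        if (sig_u > cap) { sig_u <- cap; n_capped <- n_capped + 1L }
      }
      if (ki <= length(keep_at) && it == keep_at[ki]) {
        samples[ki, ] <<- c(theta, sig_u, sig_e)
        ki <- ki + 1L
      }
    }
    n_capped
  }
  n_capped <- if (!is.null(seed)) with_seed(seed, run()) else run()
  if (n_capped > 0)
    warn_tf("%d divergent variance draws were capped", n_capped)
  ns <- nrow(samples)
  fixed <- do.call(rbind, lapply(seq_len(p), function(j) {
    s <- samples[, j]
    pm <- 2 * min(mean(s > 0), mean(s < 0))
    data.frame(term = colnames(samples)[j], mean = mean(s),
               l95 = unname(quantile(s, 0.025)),
               u95 = unname(quantile(s, 0.975)),
               pMCMC = max(pm, 1 / ns), ess = ess_one(s))
  }))
  summ <- function(s) c(mean = mean(s), l95 = unname(quantile(s, 0.025)),
                        u95 = unname(quantile(s, 0.975)))
  out <- list(fixed = fixed,
              sigma2_u = if (q > 0) summ(samples[, "sigma2_u"]) else NULL,
              sigma2_e = summ(samples[, "sigma2_e"]),
              n_samples = ns, n_capped = n_capped, samples = samples)
  class(out) <- "posterior_summary"
  out
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat("<posterior_summary>", x$n_samples, "retained samples\n")
  df <- x$fixed
  df$mean <- round(df$mean, 3); df$l95 <- round(df$l95, 3)
  df$u95 <- round(df$u95, 3); df$pMCMC <- signif(df$pMCMC, 3)
  df$ess <- round(df$ess)
  print(df, row.names = FALSE)
  if (!is.null(x$sigma2_u))
    cat("  sigma2_u mean:", signif(x$sigma2_u[["mean"]], 3), "\n")
  cat("  sigma2_e mean:", signif(x$sigma2_e[["mean"]], 3), "\n")
  invisible(x)
}

acclim_design <- function(records, response, terms) {
  d <- records
  d$delta_msum <- d$post_msum - d$pre_msum
  d$cold <- as.numeric(d$treatment == "cold")
  d$mb_std <- standardize_2sd(d$pre_mb)
  d$trange_std <- standardize_2sd(d$trange)
  X <- model.matrix(terms, data = d)
  list(y = d[[response]], X = X, d = d)
}

#' Bayesian mixed model for acclimation flexibility
#'
#' Fits the focal model of the acclimation analysis: change in summit
#' metabolism (post- minus pre-acclimation) on pre-acclimation body mass,
#' temperature treatment, native annual temperature range and the
#' treatment x T_range interaction, with a population random effect whose
#' covariance derives from pairwise F_ST.  Continuous predictors are
#' standardized by two standard deviations; treatment is coded
#' control = 0, cold = 1.
#'
#' @param records acclimation table (`population`, `treatment`, `pre_mb`,
#'   `pre_msum`, `post_msum`, `trange`).
#' @param fst `fst_matrix` or theta matrix for the populations.
#' @param n_iter,burn_in,thin,seed passed to [gibbs_lmm()].
#' @param ... further arguments to [gibbs_lmm()].
#' @return A `posterior_summary` (fixed-effect terms: intercept, `mb_std`,
#'   `cold`, `trange_std`, `cold:trange_std`).
#' @export
fit_delta_model <- function(records, fst, n_iter = 1e6, burn_in = 1e4,
                            thin = 100, seed = NULL, ...) {
  dz <- acclim_design(records, "delta_msum",
                      ~ mb_std + cold + trange_std + cold:trange_std)
  pops <- sort(unique(as.character(records$population)))
  Z <- outer(as.character(records$population), pops, `==`) * 1
  colnames(Z) <- pops
  S <- fst_covariance(fst)$S[pops, pops]
  gibbs_lmm(dz$y, dz$X, Z = Z, S = S, n_iter = n_iter, burn_in = burn_in,
            thin = thin, seed = seed, ...)
}

#' Pre-acclimation companion checks
#'
#' The verification models run before interpreting the treatment effects:
#' pre-acclimation M_sum and M_b each regressed on treatment and on
#' T_range (and, when a season column exists, M_sum on season with M_b as
#' covariate), all with the same F_ST-structured population random effect.
#'
#' @inheritParams fit_delta_model
#' @return named list of `posterior_summary` objects.
#' @export
fit_pre_checks <- function(records, fst, n_iter = 1e5, burn_in = 1e4,
                           thin = 50, seed = NULL, ...) {
  pops <- sort(unique(as.character(records$population)))
  Z <- outer(as.character(records$population), pops, `==`) * 1
  colnames(Z) <- pops
  S <- fst_covariance(fst)$S[pops, pops]
  one <- function(response, terms) {
    dz <- acclim_design(records, response, terms)
    gibbs_lmm(dz$y, dz$X, Z = Z, S = S, n_iter = n_iter,
              burn_in = burn_in, thin = thin, seed = seed, ...)
  }
  out <- list(
    msum_treatment = one("pre_msum", ~ cold),
    mb_treatment = one("pre_mb", ~ cold),
    msum_trange = one("pre_msum", ~ trange_std),
    mb_trange = one("pre_mb", ~ trange_std)
  )
  if ("season" %in% names(records) && length(unique(records$season)) > 1)
    out$msum_season <- one("pre_msum", ~ season + mb_std)
  out
}

#' Coefficient of variation, as a percentage
#'
#' `100 * sd / mean` with the n-1 standard deviation; undefined (NA with a
#' warning) when the mean is numerically zero.
#'
#' @param values numeric vector, `n >= 2`.
#' @return CV in percent.
#' @export
cv_percent <- function(values) {
  if (length(values) < 2) stop_tf("need n >= 2")
  m <- mean(values)
  if (abs(m) < 1e-12) {
    warn_tf("mean is ~0; CV undefined")
    return(NA_real_)
  }
  100 * sd(values) / m
}

#' Regress within-population CV of flexibility on T_range
#'
#' Simple linear regression of the per-population coefficient of variation
#' of flexibility on the native annual temperature range; run separately
#' per treatment group by the caller.
#'
#' @param cv numeric CVs (%), one per population.
#' @param trange native annual temperature range (degC), same order.
#' @return list `r2`, `beta` (% per degC), `se`, `p`, `n`, `fit`.
#' @export
cv_vs_trange <- function(cv, trange) {
  if (length(cv) < 3) stop_tf("need n >= 3 populations")
  fit <- lm(cv ~ trange)
  sm <- summary(fit)
  list(r2 = sm$r.squared, beta = coef(fit)[["trange"]],
       se = sm$coefficients["trange", "Std. Error"],
       p = sm$coefficients["trange", "Pr(>|t|)"], n = length(cv), fit = fit)
}

#' Paired t-test on pre/post measurements
#'
#' Two-sided paired t-test on `post - pre` differences with `df = n - 1`.
#'
#' @param pre,post paired numeric vectors.
#' @return list `t`, `df`, `p`, `n`, `mean_diff`.
#' @export
paired_ttest <- function(pre, post) {
  ok <- complete.cases(pre, post)
  d <- post[ok] - pre[ok]
  if (sd(d) == 0 && all(d == 0))
    return(list(t = 0, df = length(d) - 1, p = 1, n = length(d),
                mean_diff = 0))
  tt <- t.test(post[ok], pre[ok], paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, n = sum(ok), mean_diff = unname(tt$estimate))
}
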