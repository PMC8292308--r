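#' Generate hierarchical island-model genotypes with a planted
#' environmental cline
#'
#' Neutral loci follow a two-level Balding-Nichols model mirroring a
#' radiation with deep lineage splits: an ancestral frequency per locus, a
#' lineage frequency drawn as `Beta(p(1-F_L)/F_L, (1-p)(1-F_L)/F_L)`, and a
#' population frequency drawn the same way around the lineage value with
#' `F_W`.  The two levels combine as `(1-F) = (1-F_L)(1-F_W)` so the `fst`
#' target is the total differentiation among populations; the lineage level
#' takes the fraction `lineage_fst_frac` of it.  Lineages are interleaved
#' across the environmental gradient (population i belongs to lineage
#' `i mod n_lineages`), so the deepest structure axes -- the ones later
#' conditioned out -- are not the cline itself, while the gradient still
#' varies within lineages.  Adaptive loci override the hierarchy: their
#' population frequency is logit-linear in the planted site variable
#' (`env_effect` logits per SD).  Genotypes are binomial draws; per-site
#' mean depth and missing-completely-at-random missingness are attached so
#' the variant filters can be exercised.
#'
#' @param cfg a [sim_config()]; `cfg$genotype` holds the parameters.
#' @param env numeric vector of the planted environmental variable, one
#'   value per population.  Default: an evenly spaced gradient.
#' @return A [geno_matrix()] with attribute `truth` (adaptive locus indices,
#'   population allele frequencies, lineage assignment, the environmental
#'   values used).
#' @export
gen_genotypes <- function(cfg, env = NULL) {
  g <- cfg$genotype
  env <- env %||% seq(-1, 1, length.out = g$n_pops)
  if (length(env) != g$n_pops)
    stop_tf("need one env value per population (%d)", g$n_pops)
  with_seed(cfg$seed + 307L, {
    npop <- g$n_pops; nind <- g$n_per_pop; L <- g$n_loci
    pops <- sprintf("P%d", seq_len(npop))
    pop <- factor(rep(pops, each = nind), levels = pops)
    ids <- sprintf("%s_i%02d", pop, rep(seq_len(nind), npop))
    F <- g$fst
    n_lin <- max(1L, min(g$n_lineages %||% 1L, npop))
    lineage <- rep(seq_len(n_lin), length.out = npop)
    F_L <- if (n_lin > 1) g$lineage_fst_frac * F else 0
    F_W <- 1 - (1 - F) / (1 - F_L)
    p_anc <- runif(L, g$anc_freq_range[1], g$anc_freq_range[2])
    bn <- function(p, Fc, k) {
      if (Fc <= 0) return(matrix(rep(p, each = k), nrow = k))
      matrix(rbeta(k * length(p), rep(p, each = k) * (1 - Fc) / Fc,
                   rep(1 - p, each = k) * (1 - Fc) / Fc),
             nrow = k, ncol = length(p))
    }
    p_lin <- bn(p_anc, F_L, n_lin)
    pf <- matrix(NA_real_, npop, L)
    for (i in seq_len(npop))
      pf[i, ] <- bn(p_lin[lineage[i], ], F_W, 1L)
    n_ad <- g$n_adaptive
    adaptive <- integer(0)
    if (n_ad > 0) {
      adaptive <- sort(sample.int(L, n_ad))
      z <- drop(scale(env))
      lg <- qlogis(p_anc[adaptive])
      pa <- plogis(outer(z, lg, function(zi, l) l + g$env_effect * zi))
      clip <- pa < 1e-3 | pa > 1 - 1e-3
      if (any(clip)) {
        pa <- pmin(pmax(pa, 1e-3), 1 - 1e-3)
        warn_tf("env effect pushed %d adaptive frequencies outside (0.001, 0.999); clipped",
                sum(clip))
      }
      pf[, adaptive] <- pa
    }
    geno <- matrix(rbinom(npop * nind * L, 2, pf[rep(seq_len(npop), each = nind), ]),
                   nrow = npop * nind, ncol = L,
                   dimnames = list(ids, sprintf("snp%05d", seq_len(L))))
    depth <- rlnorm(L, log(g$depth_mean), g$depth_sdlog)
    if (g$missing_rate > 0) {
      rate <- runif(L, 0, 2 * g$missing_rate)
      miss <- matrix(runif(length(geno)) <
                       rep(rate, each = nrow(geno)), nrow(geno))
      geno[miss] <- NA_integer_
    }
    coords <- data.frame(site = pops,
                         lat = 31 + 3.2 * seq_len(npop) + runif(npop, -0.5, 0.5),
                         lon = -122 + 7.5 * seq_len(npop) + runif(npop, -0.5, 0.5))
    out <- geno_matrix(geno, depth = depth, pop = pop, species = pop,
                       coords = coords)
    attr(out, "truth") <- list(adaptive = adaptive, pop_freq = pf,
                               lineage = setNames(lineage, pops), env = env)
    out
  })
}

#' Generate a complete genotype-environment association dataset
#'
#' Combines [gen_genotypes()] with a locality-level climate design that
#' mirrors range-wide specimen sampling: each population is sampled at
#' several localities whose annual temperature range (BIO7) scatters
#' around the population value that drives the planted allele-frequency
#' cline, and the competing climate variables are drawn at the locality
#' level under the pairwise-correlation and variance-inflation constraints
#' a pruned variable set satisfies (|r| < `r_max`, VIF < `vif_max`).
#'
#' @param cfg a [sim_config()].
#' @param n_loc_per_pop sampling localities per population.
#' @param bio7_pop population-level annual temperature range (degC);
#'   default an even spread over 24-45.
#' @param r_max,vif_max collinearity constraints for the generated
#'   climate table.
#' @return list `geno` (a [geno_matrix()]), `bioclim` (locality-level
#'   table), `locality` (locality of each individual), `clim_vars` (the
#'   eight variable names) and `truth`.
#' @export
gen_gea_dataset <- function(cfg, n_loc_per_pop = 4, bio7_pop = NULL,
                            r_max = 0.70, vif_max = 5) {
  g <- cfg$genotype
  npop <- g$n_pops
  bio7_pop <- bio7_pop %||% seq(24, 45, length.out = npop)
  geno <- gen_genotypes(cfg, env = drop(scale(bio7_pop)))
  clim_vars <- c("bio2", "bio7", "bio8", "bio9", "bio10", "bio14",
                 "bio18", "bio19")
  with_seed(cfg$seed + 467L, {
    locs <- sprintf("P%d_L%d", rep(seq_len(npop), each = n_loc_per_pop),
                    rep(seq_len(n_loc_per_pop), npop))
    bio7_loc <- rep(bio7_pop, each = n_loc_per_pop) +
      runif(npop * n_loc_per_pop, -1.5, 1.5)
    bio <- gen_bioclim(cfg, locs, bio7 = bio7_loc, r_max = r_max)
    locality <- unlist(lapply(seq_len(npop), function(i)
      sample(locs[(i - 1) * n_loc_per_pop + seq_len(n_loc_per_pop)],
             g$n_per_pop, replace = TRUE)))
    # the collinearity screen runs on the specimen-level expansion (each
    # individual carries its locality's climate): redraw the worst
    # competitor until the expanded set clears the VIF guard
    idx <- match(locality, bio$site)
    for (try in 1:300) {
      v <- vif(bio[idx, clim_vars])
      if (max(v) < 0.9 * vif_max) break
      worst <- names(which.max(v[setdiff(clim_vars, "bio7")]))
      lim <- range(bio[[worst]])
      bio[[worst]] <- runif(nrow(bio), lim[1], lim[2])
    }
    if (max(vif(bio[idx, clim_vars])) >= 0.9 * vif_max)
      stop_tf("could not generate climate set with VIF < %g", vif_max)
    truth <- attr(geno, "truth")
    truth$bio7_pop <- bio7_pop
    list(geno = geno, bioclim = bio, locality = locality,
         clim_vars = clim_vars, truth = truth)
  })
}

#' Generate a site-level bioclim table
#'
#' Produces the climate variables the genotype-environment association uses
#' (the eight low-correlation variables retained in the study design: BIO2,
#' BIO7, BIO8, BIO9, BIO10, BIO14, BIO18, BIO19) plus BIO1 and elevation.
#' BIO7 (temperature annual range) takes the supplied values; the remaining
#' retained variables are drawn on realistic scales and redrawn until every
#' pairwise correlation stays below `r_max`, emulating a variable set that
#' has already passed the redundancy screen.
#'
#' @param cfg a [sim_config()].
#' @param sites character vector of site/population identifiers.
#' @param bio7 numeric annual temperature range per site (degC); default an
#'   even spread over 24-45.
#' @param r_max maximum tolerated pairwise |r| among the retained variables.
#' @return data.frame with one row per site.
#' @export
gen_bioclim <- function(cfg, sites, bio7 = NULL, r_max = 0.70) {
  n <- length(sites)
  bio7 <- bio7 %||% seq(24, 45, length.out = n)
  with_seed(cfg$seed + 419L, {
    spec <- list(bio2 = c(8, 16), bio8 = c(0, 20), bio9 = c(-5, 25),
                 bio10 = c(10, 30), bio14 = c(0, 30), bio18 = c(50, 300),
                 bio19 = c(20, 400))
    acc <- list(bio7 = bio7)
    for (nm in names(spec)) {
      for (try in 1:500) {
        x <- runif(n, spec[[nm]][1], spec[[nm]][2])
        ok <- all(vapply(acc, function(a) abs(cor(a, x)) < r_max, logical(1)))
        if (ok) break
      }
      if (!ok) stop_tf("could not draw %s with pairwise |r| < %.2f", nm, r_max)
      acc[[nm]] <- x
    }
    data.frame(site = sites,
               elev = runif(n, 200, 2800),
               bio1 = 25 - 0.3 * bio7 + rnorm(n, 0, 2),
               bio2 = acc$bio2, bio7 = acc$bio7, bio8 = acc$bio8,
               bio9 = acc$bio9, bio10 = acc$bio10, bio14 = acc$bio14,
               bio18 = acc$bio18, bio19 = acc$bio19)
  })
}
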