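#' Genotype matrix container
#'
#' Individuals x biallelic sites, coded 0/1/2 (alternate-allele dosage) with
#' `NA` for missing calls, plus the per-site mean sequencing depth and the
#' individual-to-population / species / site maps the filters and analyses
#' need.
#'
#' @param geno integer matrix, individuals x sites, values 0/1/2/NA, with
#'   dimnames.
#' @param depth numeric vector of per-site mean depth.
#' @param pop factor of population assignments, one per individual.
#' @param species factor of species assignments (defaults to `pop`);
#'   Hardy-Weinberg filtering and imputation group by species.
#' @param coords optional data.frame `site`/`lat`/`lon` keyed by the
#'   population labels.
#' @return A `geno_matrix` list.
#' @export
geno_matrix <- function(geno, depth, pop, species = pop, coords = NULL) {
  stopifnot(is.matrix(geno))
  if (length(depth) != ncol(geno)) stop_tf("depth length != number of sites")
  if (length(pop) != nrow(geno)) stop_tf("pop length != number of individuals")
  vals <- geno[!is.na(geno)]
  if (length(vals) && !all(vals %in% 0:2))
    stop_tf("genotypes must be coded 0/1/2 or NA (biallelic)")
  out <- list(geno = geno, depth = depth, pop = factor(pop),
              species = factor(species), coords = coords)
  class(out) <- "geno_matrix"
  out
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("<geno_matrix>", nrow(x$geno), "individuals x", ncol(x$geno),
      "sites;", nlevels(x$pop), "populations;",
      sprintf("%.2f%%", 100 * mean(is.na(x$geno))), "missing\n")
  invisible(x)
}

subset_sites <- function(g, keep) {
  g$geno <- g$geno[, keep, drop = FALSE]
  g$depth <- g$depth[keep]
  g
}

site_missing_frac <- function(g) colMeans(is.na(g$geno))

minor_allele_count <- function(g) {
  alt <- colSums(g$geno, na.rm = TRUE)
  tot <- 2 * colSums(!is.na(g$geno))
  pmin(alt, tot - alt)
}

#' Exact Hardy-Weinberg test for one biallelic site
#'
#' Two-sided exact test conditional on the allele counts: the p-value sums
#' the probabilities of all heterozygote counts no more probable than the
#' observed one.  A monomorphic site returns p = 1.
#'
#' @param n_aa,n_ab,n_bb genotype counts (homozygous reference,
#'   heterozygous, homozygous alternate).
#' @return exact p-value.
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  stopifnot(n_aa >= 0, n_ab >= 0, n_bb >= 0)
  n <- n_aa + n_ab + n_bb
  if (n < 1) stop_tf("need at least one genotype")
  nA <- 2 * n_aa + n_ab
  nB <- 2 * n_bb + n_ab
  if (nA == 0 || nB == 0) return(1)
  r <- min(nA, nB)                      # rare allele count
  hets <- seq(r %% 2, r, by = 2)        # feasible heterozygote counts
  logp <- vapply(hets, function(h) {
    aa <- (nA - h) / 2; bb <- (nB - h) / 2
    if (nA <= nB) { n11 <- aa; n22 <- bb } else { n11 <- bb; n22 <- aa }
    lfactorial(n) - lfactorial(n11) - lfactorial(h) - lfactorial(n22) +
      h * log(2)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_ab, hets)]
  sum(pr[pr <= obs * (1 + 1e-9)])
}

#' Apply the variant-site filters in pipeline order
#'
#' Reproduces the SNP-filtering cascade: (1) per-site mean depth below
#' `min_mean_dp`; (2) above `max_mean_dp`; (3) minor allele count below
#' `mac`; (4) site missingness above `max_missing1`; (5) individuals with
#' more than `ind_missing_max` missing data removed; (6) site missingness
#' above `max_missing2` (recomputed after individual removal); (7) sites
#' departing from Hardy-Weinberg equilibrium (exact p < `hwe_p`) in any
#' species.  Indels are assumed absent from a 0/1/2 matrix.  The report
#' counts removals per step, so `sum(report$removed)` equals input minus
#' output sites.
#'
#' @param g a [geno_matrix()].
#' @param min_mean_dp,max_mean_dp mean-depth bounds.
#' @param mac minimum minor allele count (sites with count < `mac` drop).
#' @param max_missing1 first-pass maximum site missingness fraction.
#' @param ind_missing_max maximum individual missingness fraction.
#' @param max_missing2 second, stricter maximum site missingness fraction.
#' @param hwe_p Hardy-Weinberg exact-test threshold (site removed when any
#'   species falls below it).
#' @return list `geno` (filtered [geno_matrix()]), `report` (data.frame
#'   `step`, `removed`, `remaining`), `individuals_removed` (ids).
#' @export
filter_sites <- function(g, min_mean_dp = 5, max_mean_dp = 50, mac = 3,
                         max_missing1 = 0.5, ind_missing_max = 0.6,
                         max_missing2 = 0.05, hwe_p = 0.001) {
  report <- data.frame(step = character(0), removed = integer(0),
                       remaining = integer(0))
  note <- function(step, removed) {
    report <<- rbind(report, data.frame(step = step, removed = removed,
                                        remaining = ncol(g$geno)))
  }
  drop_sites <- function(bad, step) {
    g <<- subset_sites(g, !bad)
    note(step, sum(bad))
  }
  drop_sites(g$depth < min_mean_dp, "depth_low")
  drop_sites(g$depth > max_mean_dp, "depth_high")
  drop_sites(minor_allele_count(g) < mac, "mac")
  drop_sites(site_missing_frac(g) > max_missing1, "missing_site_pass1")

  ind_bad <- rowMeans(is.na(g$geno)) > ind_missing_max
  individuals_removed <- rownames(g$geno)[ind_bad]
  if (any(ind_bad)) {
    g$geno <- g$geno[!ind_bad, , drop = FALSE]
    g$pop <- droplevels(g$pop[!ind_bad])
    g$species <- droplevels(g$species[!ind_bad])
  }
  note("individuals_removed", 0L)  # site count unchanged at this step

  drop_sites(site_missing_frac(g) > max_missing2, "missing_site_pass2")

  hwe_bad <- vapply(seq_len(ncol(g$geno)), function(j) {
    any(vapply(levels(g$species), function(sp) {
      x <- g$geno[g$species == sp, j]
      x <- x[!is.na(x)]
      if (!length(x)) return(FALSE)
      hwe_exact_test(sum(x == 0), sum(x == 1), sum(x == 2)) < hwe_p
    }, logical(1)))
  }, logical(1))
  drop_sites(hwe_bad, "hwe")

  if (ncol(g$geno) == 0) warn_tf("all sites removed by filters")
  list(geno = g, report = report, individuals_removed = individuals_removed)
}

#' Impute missing genotypes with the species-modal genotype
#'
#' Each missing call is replaced by the most common observed genotype of
#' that individual's species at that site.  Ties break deterministically
#' toward the lower genotype code; a species-site cell with no observed
#' genotype at all is an error listing the cells.
#'
#' @param g a [geno_matrix()].
#' @param group grouping factor (defaults to the species map).
#' @return A complete [geno_matrix()]; attribute `n_imputed` gives the
#'   number of filled cells and `n_ties` the number of modal ties resolved.
#' @export
impute_major <- function(g, group = g$species) {
  geno <- g$geno
  group <- factor(group)
  n_imputed <- 0L
  n_ties <- 0L
  empty <- character(0)
  for (sp in levels(group)) {
    rows <- which(group == sp)
    block <- geno[rows, , drop = FALSE]
    nas <- is.na(block)
    cols <- which(colSums(nas) > 0)
    for (j in cols) {
      x <- block[, j]
      obs <- x[!is.na(x)]
      if (!length(obs)) {
        empty <- c(empty, sprintf("%s:%s", sp, colnames(geno)[j]))
        next
      }
      tab <- tabulate(obs + 1L, nbins = 3L)
      mode <- which(tab == max(tab)) - 1L
      if (length(mode) > 1) n_ties <- n_ties + 1L
      fill <- min(mode)
      block[is.na(x), j] <- fill
      n_imputed <- n_imputed + sum(is.na(x))
    }
    geno[rows, ] <- block
  }
  if (length(empty))
    stop_tf("no observed genotype to impute from for: %s",
            paste(empty, collapse = ", "))
  g$geno <- geno
  attr(g, "n_imputed") <- n_imputed
  attr(g, "n_ties") <- n_ties
  g
}
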