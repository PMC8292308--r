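#' Weir-Cockerham variance components for one site
#'
#' Computes the among-population (a), among-individual-within-population
#' (b) and within-individual (c) variance components of the
#' Weir-Cockerham theta estimator from per-population sample sizes, allele
#' frequencies and heterozygote proportions.
#'
#' @param n_i genotyped individuals per population.
#' @param p_i alternate-allele frequency per population.
#' @param h_i heterozygote proportion per population.
#' @return numeric `c(a, b, c)`.
#' @keywords internal
wc_components <- function(n_i, p_i, h_i) {
  r <- length(n_i)
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  c(a = a, b = b, c = hbar / 2)
}

#' Multi-population weighted Weir's theta
#'
#' Per site, Weir-Cockerham variance components are computed over the
#' populations with at least `min_n` genotyped individuals; the weighted
#' estimator is the ratio of summed components across sites,
#' `theta = sum(a) / sum(a + b + c)`.  Sites monomorphic across the
#' included populations contribute zero components.  With fewer than two
#' usable populations theta is undefined (`NA` with a warning).
#'
#' @param geno 0/1/2 matrix (individuals x sites) with `NA` missing, or a
#'   [geno_matrix()].
#' @param pop population factor (taken from the container when omitted).
#' @param min_n minimum genotyped individuals per population per site.
#' @return list `theta`, `n_sites` (sites contributing nonzero
#'   denominator), `components` (summed a, b, c).
#' @export
weir_theta <- function(geno, pop = NULL, min_n = 2) {
  if (inherits(geno, "geno_matrix")) {
    pop <- pop %||% geno$pop
    geno <- geno$geno
  }
  pop <- factor(pop)
  if (nlevels(pop) < 2) {
    warn_tf("theta undefined with a single population")
    return(list(theta = NA_real_, n_sites = 0L,
                components = c(a = NA, b = NA, c = NA)))
  }
  sums <- c(a = 0, b = 0, c = 0)
  n_sites <- 0L
  for (j in seq_len(ncol(geno))) {
    x <- geno[, j]
    ok <- !is.na(x)
    n_i <- tapply(ok, pop, sum)
    use <- which(n_i >= min_n)
    if (length(use) < 2) next
    comp <- wc_components(
      n_i = as.numeric(n_i[use]),
      p_i = vapply(use, function(k)
        sum(x[pop == levels(pop)[k]], na.rm = TRUE) / (2 * n_i[k]), numeric(1)),
      h_i = vapply(use, function(k)
        sum(x[pop == levels(pop)[k]] == 1, na.rm = TRUE) / n_i[k], numeric(1))
    )
    sums <- sums + comp
    if (sum(comp) != 0) n_sites <- n_sites + 1L
  }
  theta <- if (sum(sums) == 0) NA_real_ else sums[["a"]] / sum(sums)
  list(theta = theta, n_sites = n_sites, components = sums)
}

#' Pairwise weighted Weir's theta matrix
#'
#' Applies [weir_theta()] to every population pair.
#'
#' @inheritParams weir_theta
#' @return An `fst_matrix`: list `theta` (symmetric matrix, zero
#'   diagonal), `n_sites` (per-pair contributing site counts), `pops`.
#' @export
weir_fst_pairwise <- function(geno, pop = NULL, min_n = 2) {
  if (inherits(geno, "geno_matrix")) {
    pop <- pop %||% geno$pop
    geno <- geno$geno
  }
  pop <- factor(pop)
  pops <- levels(pop)
  k <- length(pops)
  if (k < 2) stop_tf("need >= 2 populations")
  th <- matrix(0, k, k, dimnames = list(pops, pops))
  ns <- matrix(0L, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    sel <- pop %in% pops[c(i, j)]
    w <- weir_theta(geno[sel, , drop = FALSE], droplevels(pop[sel]),
                    min_n = min_n)
    th[i, j] <- th[j, i] <- w$theta
    ns[i, j] <- ns[j, i] <- w$n_sites
  }
  out <- list(theta = th, n_sites = ns, pops = pops)
  class(out) <- "fst_matrix"
  out
}

#' @export
print.fst_matrix <- function(x, ...) {
  cat("<fst_matrix>", length(x$pops), "populations; theta range",
      signif(min(x$theta[upper.tri(x$theta)]), 3), "-",
      signif(max(x$theta[upper.tri(x$theta)]), 3), "\n")
  print(round(x$theta, 4))
  invisible(x)
}
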