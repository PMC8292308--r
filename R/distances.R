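#' Linearize an F_ST matrix
#'
#' Elementwise `theta / (1 - theta)`, the standard linearization used for
#' distance-based comparisons of population differentiation; monotone in
#' theta and zero on the diagonal.
#'
#' @param f an `fst_matrix` from [weir_fst_pairwise()] or a plain
#'   symmetric matrix with theta values < 1.
#' @return matrix of class `dist_matrix` with attribute `kind = "genetic"`.
#' @export
linearize_fst <- function(f) {
  th <- if (inherits(f, "fst_matrix")) f$theta else as.matrix(f)
  if (any(th >= 1)) stop_tf("theta must be < 1 to linearize")
  d <- th / (1 - th)
  diag(d) <- 0
  structure(d, kind = "genetic", class = c("dist_matrix", "matrix", "array"))
}

#' Great-circle distances among sampling sites
#'
#' Haversine distances on a sphere of radius 6371.0088 km (the IUGG mean
#' Earth radius; sphere-vs-ellipsoid differences are negligible at this
#' scale).
#'
#' @param sites data.frame with `site` (or rownames), `lat`, `lon` in
#'   decimal degrees.
#' @return symmetric matrix of distances in km, class `dist_matrix`,
#'   attribute `kind = "geographic"`.
#' @export
geodesic_distance <- function(sites) {
  xy <- cbind(sites$lon, sites$lat)
  d <- geosphere::distm(xy, fun = function(p1, p2)
    geosphere::distHaversine(p1, p2, r = 6371008.8)) / 1000
  labs <- sites$site %||% rownames(sites)
  dimnames(d) <- list(labs, labs)
  structure(d, kind = "geographic",
            class = c("dist_matrix", "matrix", "array"))
}

#' Euclidean environmental distances among sites
#'
#' Standardizes each retained climate variable by two standard deviations
#' and takes pairwise Euclidean norms.
#'
#' @param bioclim site-level table with a `site` column and climate
#'   variables.
#' @param variables columns to use (e.g. the retained low-correlation
#'   set).
#' @return symmetric matrix, class `dist_matrix`, `kind = "environmental"`.
#' @export
env_distance <- function(bioclim, variables) {
  Z <- sapply(variables, function(v) standardize_2sd(bioclim[[v]]))
  d <- as.matrix(dist(Z))
  labs <- bioclim$site %||% rownames(bioclim)
  dimnames(d) <- list(labs, labs)
  structure(d, kind = "environmental",
            class = c("dist_matrix", "matrix", "array"))
}

lower_tri <- function(m) m[lower.tri(m)]

#' Partial Mantel test
#'
#' Correlation between two distance matrices controlling for a third: the
#' statistic is the Pearson correlation of the off-diagonal entries of `A`
#' and `B` after both are residualized on `C`.  Significance comes from
#' jointly permuting the rows and columns of `A` (the standard Mantel
#' permutation of object labels) and recomputing the statistic; the
#' p-value is one-sided on the upper tail with the add-one convention.
#'
#' @param A,B,C square symmetric distance matrices with matching labels
#'   (when dimnames are present, `B` and `C` are aligned to `A`).
#' @param n_perm number of permutations.
#' @param seed optional seed pinning the permutation stream.
#' @return list `r`, `p`, `n` (objects), `n_perm`.
#' @export
partial_mantel <- function(A, B, C, n_perm = 999, seed = NULL) {
  A <- as.matrix(A); B <- as.matrix(B); C <- as.matrix(C)
  n <- nrow(A)
  if (n < 4) stop_tf("need >= 4 objects")
  if (!is.null(rownames(A)) && !is.null(rownames(B)))
    B <- B[rownames(A), rownames(A)]
  if (!is.null(rownames(A)) && !is.null(rownames(C)))
    C <- C[rownames(A), rownames(A)]
  rab <- function(Am) {
    a <- lower_tri(Am); b <- lower_tri(B); cc <- lower_tri(C)
    if (sd(a) == 0 || sd(b) == 0 || sd(cc) == 0)
      stop_tf("constant distance matrix: partial correlation undefined")
    ra <- lm.fit(cbind(1, cc), a)$residuals
    rb <- lm.fit(cbind(1, cc), b)$residuals
    cor(ra, rb)
  }
  r_obs <- rab(A)
  run <- function() {
    r_perm <- vapply(seq_len(n_perm), function(i) {
      p <- sample.int(n)
      rab(A[p, p])
    }, numeric(1))
    (sum(r_perm >= r_obs - 1e-12) + 1) / (n_perm + 1)
  }
  p <- if (!is.null(seed)) with_seed(seed, run()) else run()
  list(r = r_obs, p = p, n = n, n_perm = n_perm)
}
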