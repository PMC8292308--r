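#' PCA of a complete genotype matrix
#'
#' Column-centers the matrix (no variance scaling by default, so common
#' variants carry their natural weight) and extracts axes by singular value
#' decomposition; the percentage of variance per axis is the squared
#' singular value over the total.
#'
#' @param g a complete [geno_matrix()] or a plain numeric matrix.
#' @param n_axes number of axes to return (truncated to the matrix rank,
#'   with a warning, when larger).
#' @param scale also scale columns to unit variance.
#' @return list `scores` (individuals x axes), `pct_var`, `sdev`.
#' @export
pca_genotypes <- function(g, n_axes = 10, scale = FALSE) {
  G <- if (inherits(g, "geno_matrix")) g$geno else g
  if (anyNA(G)) stop_tf("PCA needs a complete matrix; impute first")
  Gc <- scale(G, center = TRUE, scale = scale)
  if (scale) Gc[, attr(Gc, "scaled:scale") == 0] <- 0
  sv <- svd(Gc)
  pos <- sv$d > max(sv$d) * 1e-10
  r <- sum(pos)
  if (n_axes > r) {
    warn_tf("n_axes = %d exceeds rank %d; truncating", n_axes, r)
    n_axes <- r
  }
  scores <- sv$u[, seq_len(n_axes), drop = FALSE] %*%
    diag(sv$d[seq_len(n_axes)], n_axes)
  rownames(scores) <- rownames(G)
  colnames(scores) <- paste0("PC", seq_len(n_axes))
  list(scores = scores,
       pct_var = 100 * sv$d[seq_len(n_axes)]^2 / sum(sv$d^2),
       sdev = sv$d / sqrt(max(1, nrow(G) - 1)))
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` comes from regressing column `j`
#' on the remaining columns (with intercept).
#'
#' @param X numeric matrix or data.frame of explanatory variables.
#' @return named numeric vector of VIFs.
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2) return(setNames(rep(1, ncol(X)), colnames(X)))
  out <- vapply(seq_len(ncol(X)), function(j) {
    r2 <- summary(lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared
    1 / max(1 - r2, 1e-12)
  }, numeric(1))
  setNames(out, colnames(X))
}

#' Greedy correlation pruning of explanatory variables
#'
#' Repeatedly finds the pair with the largest absolute correlation at or
#' above `r_max` and drops the member with the higher mean absolute
#' correlation to all remaining variables (a deterministic rule), until all
#' pairwise |r| fall below the threshold.
#'
#' @param X numeric matrix or data.frame.
#' @param r_max correlation threshold (pairs with |r| >= `r_max` conflict).
#' @return list `keep` (retained column names, original order), `dropped`
#'   (in drop order).
#' @export
correlation_prune <- function(X, r_max = 0.70) {
  X <- as.matrix(X)
  keep <- colnames(X) %||% paste0("V", seq_len(ncol(X)))
  colnames(X) <- keep
  dropped <- character(0)
  repeat {
    if (length(keep) < 2) break
    R <- abs(cor(X[, keep, drop = FALSE]))
    diag(R) <- 0
    if (max(R) < r_max) break
    ij <- which(R == max(R), arr.ind = TRUE)[1, ]
    pair <- keep[ij]
    meanr <- rowMeans(R)[ij]
    drop <- pair[which.max(meanr)]
    dropped <- c(dropped, drop)
    keep <- setdiff(keep, drop)
  }
  list(keep = keep, dropped = dropped)
}

ezekiel_adj <- function(r2, n, df) 1 - (1 - r2) * (n - 1) / (n - df - 1)

resid_on <- function(M, Z) {
  # residuals of each column of M on (intercept + Z)
  q <- qr(cbind(1, Z))
  M - qr.fitted(q, M)
}

#' Partial redundancy analysis
#'
#' Constrained ordination of a (genotype) response matrix on explanatory
#' (climatic) variables, optionally conditioned on covariates such as the
#' leading principal components of population structure.  Both response and
#' explanatory matrices are residualized on the conditioning variables
#' (with intercept); the constrained axes are the singular vectors of the
#' fitted values from the multivariate least-squares of the residualized
#' response on the residualized predictors.  Variance fractions are
#' reported raw (sums of squares over the total) and adjusted by the
#' Ezekiel small-sample correction with the appropriate degrees of freedom
#' (the conditioned fraction uses the difference of adjusted R-squares of
#' the full and conditioning-only models).  Explanatory collinearity is
#' guarded by a VIF threshold.
#'
#' @param Y response matrix (individuals x loci); centered internally.
#' @param X explanatory variables (standardized by the caller).
#' @param condition optional conditioning matrix (e.g. PC1-PC2 scores).
#' @param vif_max maximum tolerated VIF among `X` columns (error above).
#' @param scale scale `Y` columns to unit variance before analysis.
#' @return An `rda_result` list: `eig` (constrained eigenvalues, i.e.
#'   squared singular values), `scores` (individuals x axes), `loadings`
#'   (correlations of `X` with the axes), raw fractions
#'   (`prop_conditional`, `prop_constrained`, `prop_residual`, which sum to
#'   1), `r2_semipartial` (constrained over post-conditioning total),
#'   `adj_r2_constrained`, `adj_r2_conditional`, dfs, the pseudo-F, and
#'   internal matrices reused by [permutation_anova()].
#' @export
partial_rda <- function(Y, X, condition = NULL, vif_max = 5, scale = FALSE) {
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  n <- nrow(Y)
  stopifnot(nrow(X) == n)
  if (ncol(X) >= 2) {
    v <- vif(X)
    if (any(v >= vif_max))
      stop_tf("VIF >= %g for: %s", vif_max,
              paste(names(v)[v >= vif_max], collapse = ", "))
  }
  Yc <- scale(Y, center = TRUE, scale = scale)
  if (scale) Yc[is.na(Yc)] <- 0
  ss_total <- sum(Yc^2)
  q <- 0L
  if (!is.null(condition)) {
    C <- as.matrix(condition)
    q <- qr(scale(C, center = TRUE, scale = FALSE))$rank
    Yr <- resid_on(Yc, C)
    Xr <- resid_on(X, C)
  } else {
    Yr <- Yc
    Xr <- scale(X, center = TRUE, scale = FALSE)
  }
  ss_cond <- ss_total - sum(Yr^2)
  qx <- qr(Xr)
  p <- qx$rank
  fitted <- qr.fitted(qx, Yr)
  ss_constr <- sum(fitted^2)
  ss_resid <- sum(Yr^2) - ss_constr
  sv <- svd(fitted, nu = min(n, p), nv = 0)
  nax <- sum(sv$d > max(sv$d, 0) * 1e-9)
  nax <- max(nax, 1L)
  eig <- sv$d[seq_len(nax)]^2
  scores <- sv$u[, seq_len(nax), drop = FALSE] %*% diag(sv$d[seq_len(nax)], nax)
  rownames(scores) <- rownames(Y)
  colnames(scores) <- paste0("RDA", seq_len(nax))
  loadings <- suppressWarnings(cor(Xr, scores))
  df_res <- n - 1 - p - q
  pseudo_f <- (ss_constr / p) / (ss_resid / df_res)
  r2_c <- ss_cond / ss_total
  r2_cx <- (ss_cond + ss_constr) / ss_total
  adj_constr <- if (q > 0)
    ezekiel_adj(r2_cx, n, p + q) - ezekiel_adj(r2_c, n, q)
  else ezekiel_adj(r2_cx, n, p)
  adj_cond <- if (q > 0) ezekiel_adj(r2_c, n, q) else 0
  # compact representation of Yr with identical cross-products, for permutations
  svy <- svd(Yr, nv = 0)
  ry <- sum(svy$d > max(svy$d, 0) * 1e-12)
  Yred <- svy$u[, seq_len(ry), drop = FALSE] %*% diag(svy$d[seq_len(ry)], ry)
  Cc <- if (!is.null(condition))
    scale(as.matrix(condition), center = TRUE, scale = FALSE) else NULL
  out <- list(eig = eig, scores = scores, loadings = loadings,
              condition = Cc,
              prop_conditional = r2_c,
              prop_constrained = ss_constr / ss_total,
              prop_residual = ss_resid / ss_total,
              r2_semipartial = ss_constr / (ss_total - ss_cond),
              adj_r2_constrained = adj_constr,
              adj_r2_conditional = adj_cond,
              n = n, p = p, q = q, df_res = df_res, pseudo_f = pseudo_f,
              ss_total = ss_total, ss_cond = ss_cond,
              ss_constr = ss_constr, ss_resid = ss_resid,
              Xr = Xr, Yred = Yred)
  class(out) <- "rda_result"
  out
}

#' @export
print.rda_result <- function(x, ...) {
  cat("<rda_result>", x$n, "individuals,", x$p, "constrained df,",
      x$q, "conditioning df\n")
  cat("  constrained:", signif(x$prop_constrained, 4), "raw /",
      signif(x$adj_r2_constrained, 4), "adjusted R2\n")
  cat("  conditional:", signif(x$prop_conditional, 4), "raw /",
      signif(x$adj_r2_conditional, 4), "adjusted R2\n")
  cat("  pseudo-F =", signif(x$pseudo_f, 4), "\n")
  invisible(x)
}

#' Permutation tests for a partial RDA
#'
#' ANOVA-like permutation tests: the model test permutes rows of the
#' residualized explanatory matrix, re-residualizes the permuted copy on
#' the conditioning variables (the permuted design must stay orthogonal to
#' the conditioning space, like the observed one, or permuted F values are
#' systematically deflated), and recomputes the pseudo-F (constrained
#' variance per df over residual variance per df); each axis is then
#' tested marginally against the residual after the preceding axes are
#' absorbed into the conditioning set.  P-values use the add-one
#' convention `(count >= observed + 1) / (n_perm + 1)`.
#'
#' @param rda an [partial_rda()] result.
#' @param n_perm_model permutations for the whole-model test.
#' @param n_perm_axis permutations for each axis test.
#' @param n_axes how many leading axes to test.
#' @param seed optional seed pinning the permutation stream.
#' @return list `p_model`, `f_model`, `p_axis` (named vector).
#' @export
permutation_anova <- function(rda, n_perm_model = 999, n_perm_axis = 299,
                              n_axes = min(4, length(rda$eig)), seed = NULL) {
  run <- function() {
    n <- rda$n
    Yred <- rda$Yred
    C <- rda$condition
    reproj <- function(Xp, Z) if (is.null(Z)) Xp else resid_on(Xp, Z)
    f_perm <- vapply(seq_len(n_perm_model), function(i) {
      Xp <- reproj(rda$Xr[sample.int(n), , drop = FALSE], C)
      qx <- qr(Xp)
      ssf <- sum(qr.fitted(qx, Yred)^2)
      (ssf / rda$p) / ((sum(Yred^2) - ssf) / rda$df_res)
    }, numeric(1))
    p_model <- (sum(f_perm >= rda$pseudo_f - 1e-12) + 1) / (n_perm_model + 1)

    p_axis <- setNames(numeric(0), character(0))
    if (n_axes > 0) {
      denom <- rda$ss_resid / rda$df_res
      p_axis <- vapply(seq_len(n_axes), function(ax) {
        if (ax == 1) {
          Yi <- Yred; Xi <- rda$Xr; Zi <- C
        } else {
          prev <- rda$scores[, seq_len(ax - 1), drop = FALSE]
          Yi <- resid_on(Yred, prev)
          Xi <- resid_on(rda$Xr, prev)
          Zi <- if (is.null(C)) prev else cbind(C, prev)
        }
        f_obs <- rda$eig[ax] / denom
        f_p <- vapply(seq_len(n_perm_axis), function(i) {
          Xp <- reproj(Xi[sample.int(n), , drop = FALSE], Zi)
          qx <- qr(Xp)
          fit <- qr.fitted(qx, Yi)
          d1 <- svd(fit, nu = 0, nv = 0)$d[1]
          ssf <- sum(fit^2)
          d1^2 / ((sum(Yi^2) - ssf) / rda$df_res)
        }, numeric(1))
        (sum(f_p >= f_obs - 1e-12) + 1) / (n_perm_axis + 1)
      }, numeric(1))
      names(p_axis) <- paste0("RDA", seq_len(n_axes))
    }
    list(p_model = p_model, f_model = rda$pseudo_f, p_axis = p_axis)
  }
  if (!is.null(seed)) with_seed(seed, run()) else run()
}

#' Variance partitioning across explanatory variables
#'
#' Quantifies the fraction of (post-conditioning) response variance
#' attributable to each explanatory variable.  The default `marginal` mode
#' reports, per variable, the adjusted R-squared of the partial RDA
#' constrained on that variable alone (conditioned on the same covariates);
#' under collinearity these fractions sum to less than the constrained
#' total.  The `unique` mode reports instead the leave-one-out difference
#' `adjR2(all) - adjR2(all but v)`.  Rows for the constrained and
#' conditional totals are appended.
#'
#' @inheritParams partial_rda
#' @param mode `"marginal"` or `"unique"`.
#' @return data.frame `component`, `adj_r2`.
#' @export
variance_partition <- function(Y, X, condition = NULL,
                               mode = c("marginal", "unique"),
                               vif_max = 5, scale = FALSE) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  full <- partial_rda(Y, X, condition, vif_max = vif_max, scale = scale)
  vars <- colnames(X) %||% paste0("V", seq_len(ncol(X)))
  frac <- vapply(seq_len(ncol(X)), function(j) {
    if (mode == "marginal") {
      partial_rda(Y, X[, j, drop = FALSE], condition, vif_max = Inf,
                  scale = scale)$adj_r2_constrained
    } else {
      full$adj_r2_constrained -
        partial_rda(Y, X[, -j, drop = FALSE], condition, vif_max = Inf,
                    scale = scale)$adj_r2_constrained
    }
  }, numeric(1))
  rbind(data.frame(component = vars, adj_r2 = frac),
        data.frame(component = c("constrained_total", "conditional_total"),
                   adj_r2 = c(full$adj_r2_constrained,
                              full$adj_r2_conditional)))
}
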