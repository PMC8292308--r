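# Shared fixtures, built in code.

# Hand-built respirometry trace: known VO2 profile, optional drift/noise.
make_trace <- function(vo2_profile, fio2 = 0.2095, flow = 500,
                       baseline_n = 60, drift_per_s = 0, noise_sd = 0,
                       seed = NULL) {
  n_anim <- length(vo2_profile)
  n <- 2 * baseline_n + n_anim
  time_s <- seq_len(n) - 1
  ref <- fio2 + drift_per_s * time_s
  feo2 <- ref
  anim <- baseline_n + seq_len(n_anim)
  feo2[anim] <- ref[anim] - vo2_profile * (1 - ref[anim]) / flow
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    feo2 <- feo2 + rnorm(n, 0, noise_sd)
  }
  resp_trace(time_s, feo2, flow, fio2 = fio2,
             baselines = data.frame(
               start = c(1L, baseline_n + n_anim + 1L),
               end = c(baseline_n, n),
               phase = c("pre", "post")))
}

# Toy 10-site genotype matrix with enumerated filter truth:
# 3 sites fail low depth, 3 fail mac, 3 fail 50% missingness, 1 survives.
make_toy_geno <- function() {
  geno <- matrix(NA_integer_, nrow = 8, ncol = 10,
                 dimnames = list(sprintf("i%d", 1:8), sprintf("s%d", 1:10)))
  for (j in 1:3) geno[, j] <- c(0L, 1L, 2L, 1L, 0L, 1L, 2L, 1L)   # depth-fail
  for (j in 4:6) geno[, j] <- c(1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L)   # mac = 2
  for (j in 7:9) geno[, j] <- c(0L, 1L, 2L, NA, NA, NA, NA, NA)   # 5/8 missing
  geno[, 10] <- c(0L, 1L, 2L, 1L, 0L, 1L, 2L, 1L)                 # survivor
  depth <- c(2, 2, 2, rep(20, 7))
  geno_matrix(geno, depth = depth,
              pop = factor(rep(c("A", "B"), each = 4)),
              species = factor(rep("sp", 8)))
}

# All permutations of 1..n (tiny n only), for enumeration oracles.
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (sub in all_perms(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(sub, n, after = pos)
    }
  }
  out
}

# Random symmetric distance matrix with zero diagonal.
rand_dist <- function(n, labels = NULL) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- runif(n * (n - 1) / 2, 0.1, 1)
  m <- m + t(m)
  if (!is.null(labels)) dimnames(m) <- list(labels, labels)
  m
}

# Independent brute-force HWE oracle: enumerate every heterozygote count,
# probabilities from the conditional distribution written out directly.
hwe_brute <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  nA <- 2 * n_aa + n_ab
  if (nA == 0 || nA == 2 * n) return(1)
  hs <- 0:min(nA, 2 * n - nA)
  hs <- hs[(nA - hs) %% 2 == 0]
  pr <- sapply(hs, function(h) {
    aa <- (nA - h) / 2
    bb <- n - aa - h
    if (aa < 0 || bb < 0) return(0)
    exp(lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
          h * log(2) + lfactorial(nA) + lfactorial(2 * n - nA) -
          lfactorial(2 * n))
  })
  pr <- pr / sum(pr)
  obs <- pr[match(n_ab, hs)]
  sum(pr[pr <= obs * (1 + 1e-9)])
}
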