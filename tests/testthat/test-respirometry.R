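test_that("VO2 follows the steady-state equation and its linearity", {
  tr <- make_trace(rep(2, 100), flow = 500)
  tr$feo2[61:160] <- 0.2058  # plant FeO2 directly
  tr <- correct_baseline_drift(tr)
  tr$ref_o2[] <- 0.21
  vo2 <- compute_vo2(tr)
  expect_equal(vo2$vo2, rep(500 * 0.0042 / 0.79, 100), tolerance = 1e-12)

  # FeO2 = FiO2 gives zero; doubling flow doubles VO2 exactly
  tr0 <- make_trace(rep(0, 50))
  tr0 <- correct_baseline_drift(tr0)
  expect_equal(compute_vo2(tr0)$vo2, rep(0, 50))
  tr2 <- make_trace(rep(3, 50), flow = 500)
  tr2b <- make_trace(rep(3, 50), flow = 500)
  tr2b$flow <- tr2b$flow * 2
  v1 <- compute_vo2(correct_baseline_drift(tr2))$vo2
  # same fractions at doubled flow: rebuild with flow 1000 and same depletion
  d1 <- 0.2095 - (0.2095 - v1[1] * (1 - 0.2095) / 500)
  expect_equal(1000 * d1 / (1 - 0.2095), 2 * v1[1], tolerance = 1e-12)
})

test_that("baseline drift correction interpolates linearly and absorbs offsets", {
  # pre mean 0.2095, post mean 0.2085: reference at the time midpoint is 0.2090
  tr <- make_trace(rep(2, 200), baseline_n = 50)
  tr$feo2[1:50] <- 0.2095
  tr$feo2[251:300] <- 0.2085
  tr <- correct_baseline_drift(tr)
  t_mid <- (mean(tr$time_s[1:50]) + mean(tr$time_s[251:300])) / 2
  expect_equal(approx(tr$time_s, tr$ref_o2, xout = t_mid)$y, 0.2090,
               tolerance = 1e-9)
  expect_equal(attr(tr, "baseline_drift"), 0.001, tolerance = 1e-12)

  # planted linear drift: recovered M_sum matches the drift-free oracle
  prof <- c(seq(1, 6, length.out = 150), rep(6, 400),
            seq(6, 2, length.out = 150))
  for (drift in c(0, 2e-7)) {
    tr <- make_trace(prof, drift_per_s = drift)
    s <- process_trace(tr, window_s = 300)
    expect_equal(s$msum, 6, tolerance = 5e-3)
  }

  # adding a constant to FeO2 everywhere leaves M_sum unchanged
  tr <- make_trace(prof)
  s0 <- process_trace(tr, window_s = 300)$msum
  tr$feo2 <- tr$feo2 + 0.002
  s1 <- process_trace(tr, window_s = 300)$msum
  # the depletion numerator is exactly offset-invariant; the (1 - FiO2)
  # denominator shifts the result by ~0.25% for a 0.002 offset
  expect_equal(s1, s0, tolerance = 0.004)

  # missing post baseline is a QC failure, not an exception
  tr2 <- make_trace(prof)
  attr(tr2, "baselines") <- attr(tr2, "baselines")[1, , drop = FALSE]
  s <- process_trace(tr2)
  expect_false(s$qc_pass)
  expect_true("baseline_missing" %in% s$qc_reasons)
})

test_that("extract_msum equals brute-force window enumeration", {
  # plateau case
  v <- data.frame(time_s = 0:4, vo2 = c(1, 1, 5, 5, 1))
  s <- extract_msum(v, window_s = 2)
  expect_equal(s$msum, 5)
  expect_equal(s$window_start, 2)

  # constant series: any window gives the constant
  v <- data.frame(time_s = 0:99, vo2 = rep(3, 100))
  expect_equal(extract_msum(v, window_s = 30)$msum, 3)

  set.seed(42)
  for (i in 1:20) {
    n <- sample(400:700, 1)
    wn <- sample(c(60, 150, 300), 1)
    x <- rnorm(n, 5, 1)
    v <- data.frame(time_s = seq_len(n) - 1, vo2 = x)
    brute <- max(vapply(seq_len(n - wn + 1),
                        function(s) mean(x[s:(s + wn - 1)]), numeric(1)))
    expect_equal(extract_msum(v, window_s = wn)$msum, brute,
                 tolerance = 1e-12)
  }

  # too-short series fails QC
  s <- extract_msum(data.frame(time_s = 0:9, vo2 = rnorm(10)), window_s = 300)
  expect_false(s$qc_pass)
  expect_equal(s$qc_reasons, "duration")
})

test_that("QC thresholds flag drift and inconsistent flow with reasons", {
  prof <- rep(4, 400)
  tr <- make_trace(prof)
  s <- process_trace(tr, window_s = 60)
  expect_true(s$qc_pass)

  tr <- make_trace(prof)
  tr$feo2[461:520] <- tr$feo2[461:520] + 0.01  # big post-baseline shift
  s <- process_trace(tr, window_s = 60)
  expect_false(s$qc_pass)
  expect_true("baseline_drift" %in% s$qc_reasons)

  tr <- make_trace(prof)
  set.seed(1)
  tr$flow <- tr$flow * exp(rnorm(nrow(tr), 0, 0.2))
  s <- process_trace(tr, window_s = 60)
  expect_false(s$qc_pass)
  expect_true("flow" %in% s$qc_reasons)
})

test_that("traces round-trip through CSV + JSON sidecar", {
  tr <- make_trace(c(seq(1, 5, length.out = 50), rep(5, 100)),
                   noise_sd = 1e-4, seed = 7)
  d <- withr::local_tempdir()
  p <- file.path(d, "t1.csv")
  write_trace(tr, p)
  tr2 <- read_trace(p)
  expect_equal(tr2$feo2, tr$feo2, tolerance = 1e-12)
  expect_equal(attr(tr2, "fio2"), attr(tr, "fio2"))
  expect_equal(process_trace(tr2)$msum, process_trace(tr)$msum)
})
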