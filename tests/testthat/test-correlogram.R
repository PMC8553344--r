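test_that("cross-correlogram peaks at zero for identical trains and at +3 ms for a delayed copy", {
  set.seed(111)
  base <- poisson_train(30, 1)
  p <- identical_pair(base)
  cg <- cross_correlogram(p, max_lag = 0.05)
  expect_equal(cg$lags[which.max(cg$values)], 0)
  # positive tau means cell_b lags cell_a
  delayed <- event_train(base$times[base$times <= 1 - 0.003] + 0.003, 1)
  kept <- base$times <= 1 - 0.003
  pd <- pair_recording(trial_set(list(event_train(base$times[kept], 1))),
                       trial_set(list(delayed)))
  cgd <- cross_correlogram(pd, max_lag = 0.05)
  expect_equal(cgd$lags[which.max(cgd$values)], 0.003, tolerance = 1e-9)
})

test_that("independent Poisson trains give a flat baseline near the product of rates", {
  set.seed(121)
  p <- poisson_pair(40, 25, 2, 8)
  cg <- cross_correlogram(p, max_lag = 0.02)
  # unit-area kernels, no mean subtraction: E[C] = r1 * r2
  expect_equal(mean(cg$values), 40 * 25, tolerance = 0.15)
  expect_lt(stats::sd(cg$values) / mean(cg$values), 0.2)
})

test_that("correlogram symmetry: swapping the pair mirrors the lag axis", {
  set.seed(131)
  p <- poisson_pair(30, 30, 1, 3)
  ab <- cross_correlogram(p, max_lag = 0.03)
  ba <- cross_correlogram(pair_recording(p$cell_b, p$cell_a),
                          max_lag = 0.03)
  expect_equal(ab$values, rev(ba$values), tolerance = 1e-10)
  # auto-correlogram is even and maximal at zero lag
  auto <- cross_correlogram(identical_pair(p$cell_a$trains[[1]]),
                            max_lag = 0.03)
  expect_equal(auto$values, rev(auto$values), tolerance = 1e-10)
  expect_equal(auto$lags[which.max(auto$values)], 0)
})

test_that("null-corrected peak is ~0 for expt = null and strongly positive for synchrony", {
  set.seed(141)
  p <- poisson_pair(30, 30, 1, 4)
  cg <- cross_correlogram(p, max_lag = 0.05, mean_subtract = TRUE)
  expect_lte(correlogram_peak(cg, cg), 0)
  expect_equal(correlogram_peak(cg, cg), 0, tolerance = 1e-12)
  # degenerate window: value at tau = 0 only
  shifted <- cg
  shifted$values <- cg$values + 1
  expect_equal(correlogram_peak(shifted, cg, half_window = 0),
               1, tolerance = 1e-12)
  # grid mismatch errors
  other <- cross_correlogram(p, max_lag = 0.04, mean_subtract = TRUE)
  expect_error(correlogram_peak(cg, other), "lag grid")
  # synchronized pair beats its surrogate null by > 3 null SD
  ps <- synchronous_pair(sync_pair_spec(f_start = 60, f_end = 60,
                                        phase_jitter = 0.001,
                                        n_trials = 8), seed = 142)
  expt <- cross_correlogram(ps, max_lag = 0.05, mean_subtract = TRUE)
  null <- null_correlogram(ps, n_repeats = 5, seed = 143, max_lag = 0.05,
                           mean_subtract = TRUE)
  expect_gt(correlogram_peak(expt, null), 3 * stats::sd(null$values))
})

test_that("50 ms sliding average attenuates gamma but passes theta", {
  fs <- 10000
  lags <- seq(-0.25, 0.25, by = 1 / fs)
  mk <- function(f) {
    structure(list(lags = lags, values = cos(2 * pi * f * lags),
                   n_trials = 1L, fs = fs), class = "correlogram")
  }
  # moving-average transfer-function oracle: a length-N average of a
  # sampled tone passes |sin(pi f N/fs) / (N sin(pi f/fs))|
  N <- 2 * floor(0.050 * fs / 2) + 1
  H <- function(f) abs(sin(pi * f * N / fs) / (N * sin(pi * f / fs)))
  mid <- abs(lags) < 0.15
  g50 <- smooth_correlogram(mk(50), 0.050)
  expect_equal(max(abs(g50$values[mid])), H(50), tolerance = 0.02)
  expect_lt(max(abs(g50$values[mid])), 0.15)   # strong gamma attenuation
  g5 <- smooth_correlogram(mk(5), 0.050)
  expect_equal(max(g5$values[mid]), H(5), tolerance = 0.02)
  expect_gt(max(g5$values[mid]), 0.85)         # theta passes
  # constant correlogram unchanged, length preserved
  const <- mk(0)
  sm <- smooth_correlogram(const, 0.050)
  expect_equal(sm$values, const$values, tolerance = 1e-12)
  expect_length(sm$values, length(lags))
  expect_error(smooth_correlogram(const, 1e-6), "lag step")
})

test_that("surrogate-vs-surrogate corrected peaks are centered on zero", {
  set.seed(151)
  trials_a <- poisson_trial_set(25, 0.8, 5)
  trials_b <- poisson_trial_set(25, 0.8, 5)
  peaks <- vapply(1:50, function(i) {
    sa <- poisson_surrogate(trials_a, 1)[[1]]
    sb <- poisson_surrogate(trials_b, 1)[[1]]
    sa2 <- poisson_surrogate(trials_a, 1)[[1]]
    sb2 <- poisson_surrogate(trials_b, 1)[[1]]
    e <- cross_correlogram(pair_recording(sa, sb), max_lag = 0.01,
                           mean_subtract = TRUE, fs = 5000)
    n <- cross_correlogram(pair_recording(sa2, sb2), max_lag = 0.01,
                           mean_subtract = TRUE, fs = 5000)
    e$values[e$lags == 0] - n$values[n$lags == 0]
  }, numeric(1L))
  expect_lt(abs(mean(peaks)), 0.5 * stats::sd(peaks))
})
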