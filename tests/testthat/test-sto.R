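test_that("spike interpolation flattens spikes and preserves the carrier frequency", {
  fs <- 2000
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  flat <- rep(-55, length(t))
  # no spikes: unchanged
  sub0 <- interpolate_spikes(flat, fs, spike_times = numeric(0))
  expect_equal(sub0$vm, flat)
  # one spike on a flat baseline: exactly baseline afterwards
  v <- flat
  sp <- t >= 0.5 & t < 0.502
  v[sp] <- 30
  sub1 <- interpolate_spikes(v, fs, spike_threshold = -20)
  expect_equal(sub1$vm, flat, tolerance = 1e-9)
  expect_length(sub1$interpolated_spans, 1L)
  # spike riding a 40 Hz sinusoid: CWT peak stays at 40 +/- 2 Hz
  v2 <- -55 + 3 * cos(2 * pi * 40 * t)
  v2[sp] <- 30
  sub2 <- interpolate_spikes(v2, fs, spike_threshold = -20)
  sc <- morlet_cwt(sub2, freqs = 10:100)
  prof <- rowMeans(sc$mag)
  expect_equal(sc$freqs[which.max(prof)], 40, tolerance = 2.01)
})

test_that("Morlet scalogram localizes pure tones and is linear in amplitude", {
  fs <- 2000
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  v <- cos(2 * pi * 40 * t)
  sc <- morlet_cwt(v, fs)
  expect_equal(sc$freqs[which.max(rowMeans(sc$mag))], 40, tolerance = 1.01)
  sc2 <- morlet_cwt(2 * v, fs)
  expect_equal(sc2$mag, 2 * sc$mag, tolerance = 1e-9)
  # white noise: no bin dominates persistently — the longest single-bin
  # argmax run is an order of magnitude shorter than for a pure tone,
  # which holds the same bin for the entire record
  run_periods <- function(x) {
    scn <- morlet_cwt(x, fs, freqs = seq(20, 100, by = 5))
    top <- apply(scn$mag, 2, which.max)
    r <- rle(top)
    max(r$lengths / fs * scn$freqs[r$values])
  }
  set.seed(291)
  noise_runs <- vapply(1:10, function(s) run_periods(stats::rnorm(length(t))),
                       numeric(1L))
  tone_run <- run_periods(cos(2 * pi * 40 * t))
  expect_gt(tone_run, 10 * stats::median(noise_runs))
  expect_lt(stats::median(noise_runs), 5)
})

test_that("sinusoid fitting recovers phase with fixed amplitude and offset", {
  fs <- 2000
  t <- seq(0, 0.2 - 1 / fs, by = 1 / fs)
  for (phi0 in c(-2.5, -1, 0, 0.8, 2.9)) {
    seg <- -55 + 3 * cos(2 * pi * 45 * t + phi0)
    fit <- fit_sto_sinusoid(seg, fs, 45, t0 = 0)
    dphi <- atan2(sin(fit$phase - phi0), cos(fit$phase - phi0))
    expect_lt(abs(dphi) * 180 / pi, 5)
    # fitted amplitude is the segment SD = A/sqrt(2) for a pure sinusoid
    expect_equal(fit$amplitude, 3 / sqrt(2), tolerance = 0.01)
    # offset invariance of the phase
    fit2 <- fit_sto_sinusoid(seg + 12, fs, 45, t0 = 0)
    expect_equal(fit2$phase, fit$phase, tolerance = 1e-9)
  }
  expect_error(fit_sto_sinusoid(rep(1, 100), fs, 45), "zero-variance")
})

test_that("STO detection recovers programmed epochs and rejects 1-period blips", {
  st <- sto_trace(sto_epochs = data.frame(t_start = 0.5,
                                          t_end = 0.5 + 4 / 45,
                                          freq = 45, amp = 2, phase = 0),
                  noise_sd = 2 / 3, fs = 2000, seed = 301)
  sub <- interpolate_spikes(st)
  ss <- detect_stos(morlet_cwt(sub), sub)
  expect_gte(length(ss$events), 1L)
  e <- ss$events[[which.max(vapply(ss$events, `[[`, numeric(1L),
                                   "amplitude"))]]
  expect_equal(e$frequency, 45, tolerance = 2.01)
  expect_gte(e$n_periods, 2)
  # duration recovered within one oscillation period
  expect_lt(abs(e$n_periods - 4), 1)
  # a 1-period blip is always rejected
  st1 <- sto_trace(sto_epochs = data.frame(t_start = 0.5,
                                           t_end = 0.5 + 1 / 45,
                                           freq = 45, amp = 2, phase = 0),
                   noise_sd = 0, fs = 2000, seed = 302)
  sub1 <- interpolate_spikes(st1)
  ss1 <- detect_stos(morlet_cwt(sub1), sub1)
  durs <- vapply(ss1$events, `[[`, numeric(1L), "n_periods")
  expect_true(all(durs >= 2))   # nothing below the 2-period rule survives
})

test_that("two well-separated STOs at 30 and 80 Hz are both recovered", {
  st <- sto_trace(duration = 2, step_window = c(0.2, 1.8),
                  sto_epochs = data.frame(
                    t_start = c(0.4, 1.2), t_end = c(0.4 + 5 / 30,
                                                     1.2 + 5 / 80),
                    freq = c(30, 80), amp = c(2.5, 2.5), phase = 0),
                  noise_sd = 0.4, fs = 2000, seed = 311)
  sub <- interpolate_spikes(st)
  ss <- detect_stos(morlet_cwt(sub), sub)
  fr <- vapply(ss$events, `[[`, numeric(1L), "frequency")
  expect_true(any(abs(fr - 30) <= 3))
  expect_true(any(abs(fr - 80) <= 3))
  # epochs land where programmed
  e30 <- ss$events[[which.min(abs(fr - 30))]]
  expect_lt(abs(e30$t_start - 0.4), 0.08)
  # confirmed count is non-increasing in the r2 gate
  n_low <- length(detect_stos(morlet_cwt(sub), sub, r2_gate = 0.2)$events)
  n_high <- length(detect_stos(morlet_cwt(sub), sub, r2_gate = 0.8)$events)
  expect_lte(n_high, n_low)
})

test_that("noise-only traces yield no confirmed STOs under the quality gate", {
  n_events <- vapply(1:8, function(s) {
    st <- sto_trace(sto_epochs = data.frame(t_start = numeric(0),
                                            t_end = numeric(0),
                                            freq = numeric(0),
                                            amp = numeric(0),
                                            phase = numeric(0)),
                    noise_sd = 0.5, fs = 2000, seed = 320 + s)
    sub <- interpolate_spikes(st)
    length(detect_stos(morlet_cwt(sub), sub)$events)
  }, integer(1L))
  expect_lte(mean(n_events), 0.5)
})

test_that("resonance classification applies the >= 10 event rule exactly", {
  expect_equal(as.character(classify_resonant(10)), "resonant")
  expect_equal(as.character(classify_resonant(9)), "non-resonant")
  expect_equal(as.character(classify_resonant(0)), "non-resonant")
  # reconstructed proportions match the printed percentages
  expect_equal(round(100 * 11 / 12, 1), 91.7)
  expect_equal(100 * 5 / 10, 50)
})

test_that("post-STO spike phases and rate ratios extrapolate from the fit", {
  fs <- 2000
  f <- 50
  st <- sto_trace(duration = 1.5, step_window = c(0.2, 1.3),
                  sto_epochs = data.frame(t_start = 0.5,
                                          t_end = 0.5 + 5 / f,
                                          freq = f, amp = 2.5, phase = 0),
                  noise_sd = 0.3, fs = fs, seed = 331)
  sub <- interpolate_spikes(st)
  ss <- detect_stos(morlet_cwt(sub), sub)
  expect_gte(length(ss$events), 1L)
  e <- ss$events[[1]]
  # place spikes exactly at extrapolated peaks around the STO end
  k_last <- floor((2 * pi * e$frequency * e$t_end + e$phase) / (2 * pi))
  t_ref <- (2 * pi * k_last - e$phase) / (2 * pi * e$frequency)
  m <- sto_spike_metrics(ss, t_ref + (-1:2) / e$frequency)
  expect_true(all(abs(m$phases) < 10 * pi / 180))
  # one spike per period: ratio ~ 1; every other period: ~ 0.5
  expect_equal(m$mean_ratio, 1, tolerance = 0.02)
  m2 <- sto_spike_metrics(ss, t_ref + c(-2, 0, 2) / e$frequency)
  expect_equal(m2$mean_ratio, 0.5, tolerance = 0.02)
  expect_error(sto_spike_metrics(structure(list(events = list()),
                                           class = "sto_events"), 0.1),
               "at least one")
})
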