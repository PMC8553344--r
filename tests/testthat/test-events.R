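test_that("event containers enforce their invariants", {
  expect_error(event_train(c(0.1, 1.5), duration = 1), "within")
  tr <- event_train(c(0.3, 0.1, 0.2), duration = 1)
  expect_equal(tr$times, c(0.1, 0.2, 0.3))
  t1 <- trial_set(list(event_train(0.1, 1), event_train(0.2, 1)))
  expect_error(trial_set(list(event_train(0.1, 1), event_train(0.2, 2))),
               "duration")
  t2 <- trial_set(list(event_train(0.5, 1)))
  expect_error(pair_recording(t1, t2), "trial counts")
  expect_error(protocol_config(stim_onsets = c(0.2, 0.1)), "ascending")
})

test_that("Gaussian convolution yields unit-area kernels with the analytic peak", {
  tr <- event_train(0.5, duration = 1)
  cv <- convolve_events(tr, fs = 10000, sigma = 0.001)
  expect_equal(sum(cv$samples) / cv$fs, 1, tolerance = 1e-6)
  # closed-form Gaussian peak 1/(sigma sqrt(2 pi))
  expect_equal(max(cv$samples), 1 / (0.001 * sqrt(2 * pi)),
               tolerance = 1e-3)
  # empty train: all-zero signal is valid
  z <- convolve_events(event_train(numeric(0), 1), 10000, 0.001)
  expect_true(all(z$samples == 0))
  expect_error(convolve_events(tr, fs = 1000, sigma = 0.001), "fs too low")
  # mean subtraction leaves |mean| tiny relative to the signal
  ms <- convolve_events(tr, mean_subtract = TRUE)
  expect_lt(abs(mean(ms$samples)), 1e-9 * max(abs(ms$samples)))
})

test_that("convolution is linear over disjoint event sets and integral counts events", {
  set.seed(11)
  a <- sort(runif(7, 0.1, 0.45))
  b <- sort(runif(5, 0.55, 0.9))
  sa <- convolve_events(event_train(a, 1), 10000, 0.001)$samples
  sb <- convolve_events(event_train(b, 1), 10000, 0.001)$samples
  sab <- convolve_events(event_train(c(a, b), 1), 10000, 0.001)$samples
  expect_equal(sab, sa + sb, tolerance = 1e-12)
  expect_equal(sum(sab) / 10000, 12, tolerance = 1e-4)
})

test_that("sequential rates invert inter-event intervals at the later event", {
  tr <- event_train(c(0.1, 0.2, 0.4), 1)
  sr <- sequential_rates(tr)
  expect_equal(sr$rate, c(10, 5))
  expect_equal(sr$time, c(0.2, 0.4))
  expect_true(all(abs(sequential_rates(periodic_train(50, 1))$rate - 50) <
                    1e-8))
  expect_equal(nrow(sequential_rates(event_train(0.5, 1))), 0L)
  # Jensen: mean(1/ISI) > r for a Poisson train
  set.seed(21)
  pt <- poisson_train(20, 200)
  expect_gt(mean(sequential_rates(pt)$rate), 20)
})

test_that("PSTH conserves spike counts and recovers a homogeneous rate", {
  ts <- trial_set(lapply(1:10, function(i) event_train(0.05, 1)))
  lam <- psth(ts, bin = 0.001, smooth_sigma = 0.010)
  expect_equal(sum(lam$rate) * attr(lam, "bin"), 1, tolerance = 1e-6)
  # smoothing must not destroy counts (reflective edges)
  lam0 <- psth(ts, bin = 0.001, smooth_sigma = 0)
  expect_equal(sum(lam0$rate) * 0.001, 1, tolerance = 1e-12)
  set.seed(31)
  hp <- poisson_trial_set(20, 1, 20)
  lam2 <- psth(hp, bin = 0.001, smooth_sigma = 0.010)
  expect_true(all(abs(lam2$rate - 20) < 20))  # no wild excursions
  expect_equal(mean(lam2$rate), 20, tolerance = 0.15)
  empty <- trial_set(list(event_train(numeric(0), 1)))
  expect_true(all(psth(empty)$rate == 0))
})

test_that("CV2 is 0 for periodic, 1 for 10/30 ms ISIs, ~1 for Poisson, bounded, scale-free", {
  expect_true(all(cv2_series(periodic_train(50, 1))$values < 1e-8))
  tr <- event_train(c(0, 0.01, 0.04), 1)   # ISIs 10 then 30 ms
  expect_equal(cv2_series(tr)$values, 1)
  short <- cv2_series(event_train(c(0.1, 0.2), 1))
  expect_false(short$defined)
  expect_true(is.na(short$median))
  set.seed(41)
  pt <- poisson_train(100, 110)  # ~1e4 ISIs
  cv <- cv2_series(pt)
  expect_equal(mean(cv$values), 1, tolerance = 0.05)
  expect_true(all(cv$values >= 0 & cv$values <= 2))
  # invariance to time rescaling
  tr2 <- event_train(pt$times[1:100] * 3, pt$duration * 3)
  expect_equal(cv2_series(tr2)$values,
               cv2_series(event_train(pt$times[1:100], pt$duration))$values,
               tolerance = 1e-12)
})

test_that("relative rate difference spans [0, 2] with the boundary at one silent cell", {
  mk <- function(na, nb) {
    pair_recording(
      trial_set(list(event_train(seq_len(na) / (na + 1), 1))),
      trial_set(list(event_train(seq_len(nb) / (nb + 1), 1))))
  }
  expect_equal(as.numeric(relative_rate_difference(mk(10, 10))), 0)
  expect_equal(as.numeric(relative_rate_difference(mk(30, 10))), 1)
  expect_equal(as.numeric(relative_rate_difference(mk(10, 0))), 2)
  und <- relative_rate_difference(mk(0, 0))
  expect_true(is.na(und))
  expect_false(attr(und, "defined"))
})

test_that("event tables round-trip through delimited text", {
  set.seed(51)
  pairs <- list(pA = poisson_pair(20, 15, 1, 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_event_table(pairs, path)
  back <- read_event_table(path, duration = 1)
  expect_equal(names(back), "pA")
  expect_equal(back$pA$cell_a$trains[[2]]$times,
               pairs$pA$cell_a$trains[[2]]$times, tolerance = 1e-9)
  expect_equal(back$pA$n_trials, 3L)
})
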