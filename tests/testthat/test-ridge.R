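test_that("ridge threshold is the pooled band percentile", {
  sg <- make_spectrogram(matrix(2.5, nrow = 3, ncol = 5),
                         freqs = c(50, 100, 150),
                         times = seq(0, 0.02, by = 0.005))
  thr <- ridge_threshold(sg)
  expect_equal(thr$value, 2.5)
  # ~5% of pooled values exceed the 95th percentile; order-invariant
  set.seed(201)
  sgs <- lapply(1:4, function(i) {
    make_spectrogram(matrix(runif(3 * 50), nrow = 3),
                     freqs = c(50, 100, 150),
                     times = seq(0, by = 0.005, length.out = 50))
  })
  t1 <- ridge_threshold(sgs)
  t2 <- ridge_threshold(rev(sgs))
  expect_equal(t1$value, t2$value)
  pool <- unlist(lapply(sgs, function(s) s$power))
  expect_equal(mean(pool > t1$value), 0.05, tolerance = 0.01)
})

test_that("ridge tracking recovers an injected chirp with its programmed slope", {
  freqs <- seq(10, 200, by = 10)
  times <- seq(0, 0.3, by = 0.005)
  P <- matrix(stats::runif(length(freqs) * length(times), 0, 0.3),
              nrow = length(freqs))
  # chirp 90 -> 50 Hz over 150 ms starting at t = 0.05
  chirp_t <- times[times >= 0.05 & times <= 0.2]
  chirp_f <- 90 + (50 - 90) * (chirp_t - 0.05) / 0.15
  for (k in seq_along(chirp_t)) {
    fi <- which.min(abs(freqs - chirp_f[k]))
    ti <- which(times == chirp_t[k])
    P[fi, ti] <- 2 + stats::runif(1, 0, 0.2)
  }
  sg <- make_spectrogram(P, freqs, times)
  rs <- detect_ridges(sg, 1.0)
  expect_length(rs$ridges, 1L)
  expect_equal(rs$ridges[[1]]$slope, -40 / 150, tolerance = 0.2 * 40 / 150)
  # every reported bin is supra-threshold
  expect_true(all(rs$ridges[[1]]$powers >= 1.0))
})

test_that("all-subthreshold spectrograms yield no ridges; short ridges are discarded", {
  sg <- make_spectrogram(matrix(0.5, nrow = 10, ncol = 20),
                         freqs = seq(40, 130, by = 10),
                         times = seq(0, by = 0.005, length.out = 20))
  expect_length(detect_ridges(sg, 1.0)$ridges, 0L)
  # a single supra-threshold bin is below min_bins = 2
  sg$power[3, 7] <- 2
  expect_length(detect_ridges(sg, 1.0)$ridges, 0L)
  expect_length(detect_ridges(sg, 1.0, min_bins = 1L)$ridges, 1L)
})

test_that("two simultaneous constant bands are tracked as two ridges", {
  freqs <- seq(40, 200, by = 10)
  times <- seq(0, by = 0.005, length.out = 30)
  P <- matrix(0.1, nrow = length(freqs), ncol = length(times))
  P[freqs == 50, ] <- 2
  P[freqs == 160, ] <- 1.8
  sg <- make_spectrogram(P, freqs, times)
  rs <- detect_ridges(sg, 1.0)
  expect_length(rs$ridges, 2L)
  expect_setequal(round(vapply(rs$ridges, `[[`, numeric(1L), "mean_freq")),
                  c(50, 160))
  # disjoint claims: total ridge bins <= supra-threshold bins
  nb <- sum(vapply(rs$ridges, function(r) length(r$times), integer(1L)))
  expect_lte(nb, sum(P >= 1.0))
})

test_that("ridge summary pools distributions, slopes, prevalence, and occupancy", {
  freqs <- seq(40, 200, by = 10)
  times <- seq(0, by = 0.005, length.out = 40)
  P <- matrix(0, nrow = length(freqs), ncol = length(times))
  P[freqs == 60, 1:10] <- 2
  with_ridge <- detect_ridges(make_spectrogram(P, freqs, times), 1.0)
  without <- detect_ridges(
    make_spectrogram(P * 0, freqs, times), 1.0)
  sm <- ridge_summary(list(with_ridge, without),
                      protocol = protocol_config())
  expect_equal(sm$fraction_with_ridge, 0.5)
  # one constant-frequency ridge: CDF steps at 60 Hz, slope 0
  expect_equal(sm$freq_cdf(59.9), 0)
  expect_equal(sm$freq_cdf(60), 1)
  expect_equal(sm$slopes, 0)
  # occupancy: ridge spans 0-0.045 s -> first 50 ms window only
  expect_equal(unname(sm$occupancy), c(0.5, 0, 0, 0))
  empty <- ridge_summary(list(without), protocol = protocol_config())
  expect_equal(unname(empty$occupancy), rep(0, 4))
  expect_equal(empty$fraction_with_ridge, 0)
})

test_that("reconstructed prevalence fractions reproduce the printed percentages", {
  # 24/26 vs 5/16 pairs with >= 1 ridge
  expect_equal(round(100 * 24 / 26, 1), 92.3)
  frac <- c(rep(TRUE, 24), rep(FALSE, 2))
  expect_equal(100 * mean(frac), 92.3, tolerance = 0.05)
  expect_equal(100 * 5 / 16, 31.25)
})

test_that("rate-vs-ridge ratio is 1 for one spike per cycle and 0.5 for alternate cycles", {
  freqs <- seq(40, 200, by = 10)
  times <- seq(0, 0.995, by = 0.005)
  P <- matrix(0, nrow = length(freqs), ncol = length(times))
  P[freqs == 50, ] <- 2
  rs <- detect_ridges(make_spectrogram(P, freqs, times), 1.0)
  dur <- 1.2
  full <- event_train(0.1 + seq(0, 0.98, by = 1 / 50), dur)
  half <- event_train(0.1 + seq(0, 0.98, by = 2 / 50), dur)
  mk <- function(tr) {
    pair_recording(trial_set(list(tr), protocol = protocol_config()),
                   trial_set(list(tr), protocol = protocol_config()))
  }
  rv_full <- rate_vs_ridge(mk(full), rs)
  expect_equal(rv_full$overall_ratio, 1, tolerance = 0.05)
  rv_half <- rate_vs_ridge(mk(half), rs)
  expect_equal(rv_half$overall_ratio, 0.5, tolerance = 0.05)
  expect_error(rate_vs_ridge(mk(full),
                             structure(list(ridges = list(), hop = 0.005),
                                       class = "ridge_set")),
               "empty")
})

test_that("with a dataset-pooled threshold, synchronized pairs carry ridges and low-rate independent pairs mostly do not", {
  # study-like composition: strongly synchronized pairs dominate the pooled
  # threshold; independent tonic ~20 Hz pairs provide the chance level
  set.seed(301)
  sync_pairs <- lapply(1:4, function(i) {
    synchronous_pair(sync_pair_spec(f_start = 80, f_end = 60,
                                    n_trials = 5), seed = 310 + i)
  })
  null_pairs <- lapply(1:3, function(i) poisson_pair(20, 20, 1.2, 5))
  sgs <- lapply(c(sync_pairs, null_pairs), cpsd_spectrogram, t_ref = 0.1)
  thr <- ridge_threshold(sgs)
  n_ridges <- vapply(sgs, function(sg) {
    length(detect_ridges(sg, thr)$ridges)
  }, integer(1L))
  expect_true(all(n_ridges[1:4] >= 1))       # every synchronized pair
  expect_lte(sum(n_ridges[5:7] > 0), 1L)     # at most one chance detection
})
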