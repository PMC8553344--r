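# Shared fixture builders; everything is generated in code at test time.

# Homogeneous Poisson event train of rate r (Hz).
poisson_train <- function(rate, duration, label = NA_character_) {
  tt <- cumsum(stats::rexp(ceiling(rate * duration * 3 + 50), rate))
  event_train(tt[tt <= duration], duration, label)
}

poisson_trial_set <- function(rate, duration, n_trials,
                              protocol = NULL) {
  trial_set(lapply(seq_len(n_trials), function(i) {
    poisson_train(rate, duration)
  }), protocol = protocol)
}

poisson_pair <- function(rate_a, rate_b, duration, n_trials,
                         protocol = NULL) {
  pair_recording(poisson_trial_set(rate_a, duration, n_trials, protocol),
                 poisson_trial_set(rate_b, duration, n_trials, protocol))
}

# Perfectly periodic train.
periodic_train <- function(freq, duration, t0 = 0) {
  event_train(seq(t0, duration - 1e-9, by = 1 / freq), duration)
}

# A pair in which both cells hold the same single spike train (one trial).
identical_pair <- function(train) {
  pair_recording(trial_set(list(train)), trial_set(list(train)))
}

# Deterministic spectrogram skeleton for direct ridge-tracking tests.
make_spectrogram <- function(power, freqs, times, hop = NULL) {
  structure(list(power = power, freqs = freqs, times = times,
                 hop = if (is.null(hop)) diff(times[1:2]) else hop,
                 n_trials = 1L, kind = "CPSD", fs = NA_real_,
                 window = NA_real_),
            class = "spectrogram")
}
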