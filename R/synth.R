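#' Rate-matched independent Poisson surrogates
#'
#' Draws surrogate datasets from independent inhomogeneous Poisson processes
#' whose rate function lambda(t) is the PSTH of the experimental trial set.
#' Surrogates share the slow (stimulus-locked) firing-rate envelope but carry
#' no fast-timescale synchrony, so they define the chance level that
#' correlogram and spectrogram analyses subtract or threshold against.
#' Sampling uses Lewis-Shedler thinning against max lambda, which is exact
#' for a bounded rate function.
#'
#' @param trials A [trial_set()].
#' @param n_repeats Number of independent surrogate datasets.
#' @param psth_bin,psth_sigma PSTH bin width and smoothing SD (s) used for
#'   rate matching.
#' @param seed Optional integer seed for reproducibility.
#' @return List of `n_repeats` [trial_set()] objects, each with the same
#'   trial count and duration as the input.
#' @export
poisson_surrogate <- function(trials, n_repeats = 10L, psth_bin = 0.001,
                              psth_sigma = 0.010, seed = NULL) {
  stopifnot(inherits(trials, "trial_set"), n_repeats >= 1L)
  if (!is.null(seed)) set.seed(seed)
  lam <- psth(trials, bin = psth_bin, smooth_sigma = psth_sigma)
  dur <- trials$duration
  lam_max <- max(lam$rate)
  lapply(seq_len(n_repeats), function(r) {
    trains <- lapply(seq_len(trials$n_trials), function(tn) {
      if (lam_max <= 0) return(event_train(numeric(0L), dur))
      n_cand <- stats::rpois(1L, lam_max * dur)
      cand <- sort(stats::runif(n_cand, 0, dur))
      lam_at <- stats::approx(lam$time, lam$rate, xout = cand,
                              rule = 2L)$y
      keep <- stats::runif(n_cand) < lam_at / lam_max
      event_train(cand[keep], dur)
    })
    trial_set(trains, protocol = trials$protocol)
  })
}

#' Specification for a synthetic synchronized pair
#'
#' Describes the ground-truth oscillation a [synchronous_pair()] fixture is
#' built around: within each photostimulation cycle a common oscillator emits
#' peaks whose instantaneous frequency sweeps linearly from `f_start` to
#' `f_end` over `burst_len` seconds (a constant frequency when the two are
#' equal, emulating the decelerating gamma chirps seen in vivo); both cells
#' spike near oscillator peaks with Gaussian timing jitter and per-cycle-peak
#' Bernoulli participation.
#'
#' @param f_start,f_end Oscillation frequency (Hz) at the start/end of each
#'   cycle's active window.
#' @param phase_jitter Spike-timing jitter SD (s).
#' @param participation Probability that a cell fires on a given oscillator
#'   peak.
#' @param burst_len Active (phasic) window per cycle (s).
#' @param onset_delay Delay from pulse onset to the first oscillator peak (s).
#' @param n_trials Number of trials.
#' @param protocol A [protocol_config()].
#' @param pad Silent padding appended after the last cycle (s).
#' @return List of class `sync_pair_spec`.
#' @export
sync_pair_spec <- function(f_start = 80, f_end = 80, phase_jitter = 0.001,
                           participation = 0.8, burst_len = 0.150,
                           onset_delay = 0.010, n_trials = 10L,
                           protocol = protocol_config(), pad = 0.1) {
  stopifnot(f_start > 0, f_end > 0, participation >= 0, participation <= 1,
            burst_len > 0, n_trials >= 1L)
  structure(list(f_start = f_start, f_end = f_end,
                 phase_jitter = phase_jitter, participation = participation,
                 burst_len = burst_len, onset_delay = onset_delay,
                 n_trials = as.integer(n_trials), protocol = protocol,
                 pad = pad),
            class = "sync_pair_spec")
}

# Oscillator peak times within one cycle: step by the instantaneous period,
# frequency interpolated linearly across the active window.
.osc_peaks <- function(onset, spec) {
  t_rel <- 0
  peaks <- numeric(0L)
  repeat {
    f <- spec$f_start + (spec$f_end - spec$f_start) *
      min(t_rel / spec$burst_len, 1)
    peaks <- c(peaks, onset + spec$onset_delay + t_rel)
    t_rel <- t_rel + 1 / f
    if (t_rel > spec$burst_len) break
  }
  peaks
}

#' Generate a synthetic gamma-synchronized pair
#'
#' Both cells fire near the peaks of a shared per-cycle oscillator (see
#' [sync_pair_spec()]). Ground truth (per-trial oscillator peak times and the
#' programmed frequency profile) is stored in attribute `"truth"`.
#'
#' @param spec A [sync_pair_spec()].
#' @param seed Optional integer seed.
#' @return A [pair_recording()].
#' @export
synchronous_pair <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "sync_pair_spec"))
  if (!is.null(seed)) set.seed(seed)
  pr <- spec$protocol
  duration <- max(pr$stim_onsets) + pr$cycle_period + spec$pad
  peaks_by_trial <- vector("list", spec$n_trials)
  mk_cell <- function(peaks_by_trial) {
    lapply(peaks_by_trial, function(pk) {
      fire <- stats::runif(length(pk)) < spec$participation
      tt <- pk[fire]
      if (spec$phase_jitter > 0 && length(tt)) {
        tt <- tt + stats::rnorm(length(tt), sd = spec$phase_jitter)
      }
      event_train(tt[tt >= 0 & tt <= duration], duration)
    })
  }
  for (tn in seq_len(spec$n_trials)) {
    peaks_by_trial[[tn]] <- unlist(lapply(pr$stim_onsets, .osc_peaks,
                                          spec = spec))
  }
  a <- trial_set(mk_cell(peaks_by_trial), protocol = pr)
  b <- trial_set(mk_cell(peaks_by_trial), protocol = pr)
  out <- pair_recording(a, b, cell_types = c("mTC", "mTC"),
                        glomerular_relation = "homotypic")
  attr(out, "truth") <- list(peaks = peaks_by_trial, spec = spec,
                             slope_hz_per_ms =
                               (spec$f_end - spec$f_start) /
                               (spec$burst_len * 1000))
  out
}

#' Biexponential synaptic-event template
#'
#' Unit-peak rising/decaying exponential
#' `g(t) = (1 - exp(-t/tau_rise)) * exp(-t/tau_decay)` preceded by a flat
#' baseline, the abridged template used for detection during barrages.
#' Defaults: 4.0 ms total, 1.0 ms baseline, 0.4 ms rise, 3.0 ms decay,
#' 0.5 ms minimum event separation.
#'
#' @param total,baseline Template and leading-baseline duration (s).
#' @param tau_rise,tau_decay Rise/decay time constants (s).
#' @param min_separation Minimum separation between detected events (s).
#' @return List of class `ipsc_template`.
#' @export
ipsc_template <- function(total = 0.004, baseline = 0.001,
                          tau_rise = 0.0004, tau_decay = 0.003,
                          min_separation = 0.0005) {
  stopifnot(total > baseline, tau_rise > 0, tau_decay > 0)
  structure(list(total = total, baseline = baseline, tau_rise = tau_rise,
                 tau_decay = tau_decay, min_separation = min_separation),
            class = "ipsc_template")
}

# Unit-peak template shape evaluated at times t >= 0 after event onset.
.template_shape <- function(t, tmpl) {
  g <- (1 - exp(-t / tmpl$tau_rise)) * exp(-t / tmpl$tau_decay)
  tp <- tmpl$tau_rise * log(1 + tmpl$tau_decay / tmpl$tau_rise)
  gmax <- (1 - exp(-tp / tmpl$tau_rise)) * exp(-tp / tmpl$tau_decay)
  g / gmax
}

# Sampled detection template: flat baseline then the unit-peak shape.
.template_vector <- function(tmpl, fs) {
  n <- round(tmpl$total * fs)
  tt <- (seq_len(n) - 1L) / fs
  shape <- ifelse(tt < tmpl$baseline, 0,
                  .template_shape(tt - tmpl$baseline, tmpl))
  shape
}

#' Synthesize an IPSC current trace
#'
#' Sum of unit-peak template waveforms scaled by per-event amplitudes plus
#' white noise, outward-positive. Overlapping events sum. Ground truth is in
#' attribute `"truth"`.
#'
#' @param event_times Event onset times (s).
#' @param amplitudes Peak amplitudes (pA), positive, recycled to match.
#' @param duration Trace duration (s).
#' @param template An [ipsc_template()] (its baseline segment is not part of
#'   the simulated waveform; events rise at `event_times`).
#' @param noise_sd White-noise SD (pA).
#' @param fs Sampling rate (Hz).
#' @param seed Optional integer seed.
#' @return List of class `ipsc_trace`: `current` (pA), `times`, `fs`.
#' @export
ipsc_trace <- function(event_times, amplitudes, duration,
                       template = ipsc_template(), noise_sd = 1, fs = 10000,
                       seed = NULL) {
  stopifnot(all(amplitudes > 0))
  if (!is.null(seed)) set.seed(seed)
  amplitudes <- rep_len(amplitudes, length(event_times))
  n <- round(duration * fs)
  x <- if (noise_sd > 0) stats::rnorm(n, sd = noise_sd) else numeric(n)
  span <- round(5 * template$tau_decay * fs)  # waveform support after onset
  tt <- (0:span) / fs
  shape <- .template_shape(tt, template)
  for (k in seq_along(event_times)) {
    i0 <- round(event_times[k] * fs) + 1L
    idx <- i0:(i0 + span)
    keep <- idx >= 1L & idx <= n
    x[idx[keep]] <- x[idx[keep]] + amplitudes[k] * shape[keep]
  }
  out <- structure(list(current = x, times = (seq_len(n) - 1L) / fs,
                        fs = fs),
                   class = "ipsc_trace")
  attr(out, "truth") <- list(event_times = event_times,
                             amplitudes = amplitudes, noise_sd = noise_sd)
  out
}

#' Synthesize a step-current voltage response with subthreshold oscillations
#'
#' Baseline + step depolarization + sinusoidal STO epochs + stereotyped
#' spikes (2 ms triangular excursions to +30 mV) inserted at requested times,
#' plus white noise. Used as the round-trip fixture for the STO pipeline.
#'
#' @param duration Trace duration (s).
#' @param step_window Length-2 interval (s) of the depolarizing step.
#' @param step_dv Step depolarization (mV).
#' @param baseline_mv Resting potential (mV).
#' @param sto_epochs Data frame with columns `t_start`, `t_end`, `freq` (Hz),
#'   `amp` (mV), `phase` (rad, cosine convention; the STO is
#'   `amp * cos(2*pi*freq*(t - t_start) + phase)`).
#' @param spike_times Spike apex times (s), may be empty.
#' @param noise_sd Noise SD (mV).
#' @param fs Sampling rate (Hz).
#' @param seed Optional integer seed.
#' @return List of class `vm_trace`: `vm` (mV), `times`, `fs`, with ground
#'   truth in attribute `"truth"`.
#' @export
sto_trace <- function(duration = 1.5, step_window = c(0.25, 1.25),
                      step_dv = 15, baseline_mv = -60,
                      sto_epochs = data.frame(t_start = 0.5, t_end = 0.6,
                                              freq = 45, amp = 2, phase = 0),
                      spike_times = numeric(0L), noise_sd = 0.5, fs = 2000,
                      seed = NULL) {
  stopifnot(all(sto_epochs$freq >= 10 & sto_epochs$freq <= 150))
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration * fs)
  t <- (seq_len(n) - 1L) / fs
  v <- rep(baseline_mv, n)
  instep <- t >= step_window[1L] & t < step_window[2L]
  v[instep] <- v[instep] + step_dv
  if (nrow(sto_epochs)) {
    for (k in seq_len(nrow(sto_epochs))) {
      e <- sto_epochs[k, ]
      sel <- t >= e$t_start & t < e$t_end
      v[sel] <- v[sel] +
        e$amp * cos(2 * pi * e$freq * (t[sel] - e$t_start) + e$phase)
    }
  }
  if (noise_sd > 0) v <- v + stats::rnorm(n, sd = noise_sd)
  # stereotyped spike: 2 ms triangular excursion to +30 mV
  half <- max(1L, round(0.001 * fs))
  for (sp in spike_times) {
    ic <- round(sp * fs) + 1L
    idx <- (ic - half):(ic + half)
    keep <- idx >= 1L & idx <= n
    tri <- 1 - abs(idx - ic) / half
    v[idx[keep]] <- pmax(v[idx[keep]],
                         v[idx[keep]] + (30 - v[idx[keep]]) * tri[keep])
  }
  out <- structure(list(vm = v, times = t, fs = fs), class = "vm_trace")
  attr(out, "truth") <- list(sto_epochs = sto_epochs,
                             spike_times = spike_times,
                             step_window = step_window, step_dv = step_dv,
                             noise_sd = noise_sd)
  out
}
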