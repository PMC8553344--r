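# Coerce trial traces to a trials x samples matrix.
.as_trials <- function(traces) {
  if (is.matrix(traces)) return(traces)
  if (is.list(traces)) return(do.call(rbind, traces))
  matrix(traces, nrow = 1L)
}

#' Latency from stimulus onset to synaptic input
#'
#' First time in the response window at which the trial-mean,
#' baseline-subtracted current deviates below `-k_sd` baseline standard
#' deviations (inward-negative convention). Returns `NA` if the threshold is
#' never crossed.
#'
#' @param traces Trials x samples matrix (or list of trials) of current (pA).
#' @param fs Sampling rate (Hz).
#' @param baseline Length-2 interval (s) preceding stimulation (>= 20 ms).
#' @param response Length-2 interval (s) searched for the deflection.
#' @param k_sd Threshold in baseline SDs; 0 degenerates to the first sample
#'   below the baseline mean.
#' @return Latency (s) relative to the start of the response window, or NA.
#' @export
onset_latency <- function(traces, fs, baseline, response, k_sd = 2) {
  tr <- .as_trials(traces)
  m <- colMeans(tr)
  t <- (seq_along(m) - 1L) / fs
  bsel <- t >= baseline[1L] & t < baseline[2L]
  if (diff(baseline) < 0.020 - 1e-12) stop("baseline must be >= 20 ms")
  # SD of the raw baseline current, pooled across trials; the trial-mean
  # trace is compared against this scale
  bl_sd <- stats::sd(as.numeric(tr[, bsel]))
  if (bl_sd == 0) stop("zero baseline SD")
  x <- m - mean(m[bsel])
  rsel <- which(t >= response[1L] & t < response[2L])
  hit <- rsel[x[rsel] < -k_sd * bl_sd][1L]
  if (is.na(hit)) return(NA_real_)
  t[hit] - response[1L]
}

#' Charge transferred during a response window
#'
#' Integral of the baseline-subtracted current over the response window
#' (trapezoid-free running sum x dt). With current in pA and time in
#' seconds, the result is in pC. `polarity = "inward"` flips the sign so
#' inward charge is reported positive.
#'
#' @inheritParams onset_latency
#' @param polarity `"outward"` (default, sign kept) or `"inward"`.
#' @return Charge (pA * s = pC).
#' @export
charge_transfer <- function(traces, fs, baseline, response,
                            polarity = c("outward", "inward")) {
  polarity <- match.arg(polarity)
  m <- colMeans(.as_trials(traces))
  t <- (seq_along(m) - 1L) / fs
  x <- m - mean(m[t >= baseline[1L] & t < baseline[2L]])
  q <- sum(x[t >= response[1L] & t < response[2L]]) / fs
  if (polarity == "inward") -q else q
}

# Sub-sample spike-threshold crossing time via cubic interpolation around
# the first suprathreshold sample, evaluated on a 1 MHz grid.
.spike_crossing <- function(v, fs, threshold) {
  i <- which(v >= threshold)[1L]
  if (is.na(i) || i < 3L || i > length(v) - 2L) {
    return(if (is.na(i)) NA_real_ else (i - 1L) / fs)
  }
  idx <- (i - 2L):(i + 1L)
  tt <- (idx - 1L) / fs
  fine <- seq(tt[1L], tt[4L], by = 1e-6)
  vf <- stats::spline(tt, v[idx], xout = fine, method = "natural")$y
  j <- which(vf >= threshold)[1L]
  if (is.na(j)) (i - 1L) / fs else fine[j]
}

#' Unitary postsynaptic response amplitude
#'
#' Aligns postsynaptic trials on the presynaptic spike time (located as the
#' -40 mV upward crossing on a cubic-interpolated 1 MHz grid), averages the
#' baseline-subtracted aligned traces, and reports the maximum
#' depolarization within 15 ms of the spike. Trials without a presynaptic
#' spike are excluded and counted.
#'
#' @param post_traces,pre_traces Trials x samples matrices (mV).
#' @param fs Sampling rate (Hz).
#' @param spike_threshold Absolute presynaptic spike threshold (mV).
#' @param window Post-spike search window (s).
#' @param baseline_span Pre-spike span averaged as baseline (s).
#' @return List of class `unitary_response`: `amplitude_mv`, `mean_trace`
#'   (aligned, baseline-subtracted), `t` (s, 0 = spike), `n_used`,
#'   `n_excluded`.
#' @export
unitary_amplitude <- function(post_traces, pre_traces, fs,
                              spike_threshold = -40, window = 0.015,
                              baseline_span = 0.005) {
  post <- .as_trials(post_traces)
  pre <- .as_trials(pre_traces)
  stopifnot(nrow(post) == nrow(pre), ncol(post) == ncol(pre))
  tq <- seq(-baseline_span, window, by = 1 / fs)
  segs <- matrix(NA_real_, nrow = nrow(post), ncol = length(tq))
  n_excl <- 0L
  t <- (seq_len(ncol(post)) - 1L) / fs
  for (tr in seq_len(nrow(post))) {
    ts <- .spike_crossing(pre[tr, ], fs, spike_threshold)
    if (is.na(ts)) {
      n_excl <- n_excl + 1L
      next
    }
    segs[tr, ] <- stats::approx(t, post[tr, ], xout = ts + tq,
                                rule = 2L)$y
  }
  used <- stats::complete.cases(segs)
  if (!any(used)) stop("no trial contained a presynaptic spike")
  m <- colMeans(segs[used, , drop = FALSE])
  m <- m - mean(m[tq < 0])
  structure(list(amplitude_mv = max(m[tq > 0 & tq <= window]),
                 mean_trace = m, t = tq,
                 n_used = sum(used), n_excluded = n_excl),
            class = "unitary_response")
}

#' Electrical coupling coefficient
#'
#' Ratio of postsynaptic to presynaptic steady-state membrane-potential
#' change following a hyperpolarizing step injected into the presynaptic
#' cell. Steady state is the last 20% of the step window; each deflection is
#' the trial-averaged steady-state mean minus the baseline mean.
#'
#' @param pre_traces,post_traces Trials x samples matrices (mV).
#' @param fs Sampling rate (Hz).
#' @param baseline Length-2 pre-step interval (s).
#' @param step_window Length-2 step interval (s).
#' @param noise_mult Error if `|dV_pre|` is below `noise_mult` x the
#'   baseline SD of the presynaptic mean trace.
#' @return Coupling coefficient (dimensionless).
#' @export
coupling_coefficient <- function(pre_traces, post_traces, fs, baseline,
                                 step_window, noise_mult = 3) {
  mpre <- colMeans(.as_trials(pre_traces))
  mpost <- colMeans(.as_trials(post_traces))
  t <- (seq_along(mpre) - 1L) / fs
  ss <- c(step_window[2L] - 0.2 * diff(step_window), step_window[2L])
  bsel <- t >= baseline[1L] & t < baseline[2L]
  ssel <- t >= ss[1L] & t < ss[2L]
  dv_pre <- mean(mpre[ssel]) - mean(mpre[bsel])
  dv_post <- mean(mpost[ssel]) - mean(mpost[bsel])
  if (abs(dv_pre) <= noise_mult * stats::sd(mpre[bsel])) {
    stop("presynaptic deflection below the noise floor")
  }
  dv_post / dv_pre
}
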