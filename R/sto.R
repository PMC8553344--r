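#' Isolate the subthreshold membrane potential by interpolating across spikes
#'
#' Each spike span — from 1 ms before its threshold crossing until the
#' voltage returns within 1 mV of the pre-spike level (capped at +10 ms) —
#' is replaced by a straight line between the span endpoints. Overlapping
#' spans are merged.
#'
#' @param vm Numeric membrane-potential trace (mV) or a [sto_trace()]
#'   object.
#' @param fs Sampling rate (Hz); taken from the object if given.
#' @param spike_times Spike times (s); if NULL, upward crossings of
#'   `spike_threshold` are used.
#' @param spike_threshold Detection threshold (mV) when `spike_times` is
#'   NULL.
#' @param pre Span start before the crossing (s).
#' @param cap Maximum span length after the crossing (s).
#' @param return_tol Return tolerance to the pre-spike level (mV).
#' @return Object of class `subthreshold_trace`: `vm`, `times`, `fs`,
#'   `interpolated_spans` (list of `c(t_start, t_end)`).
#' @export
interpolate_spikes <- function(vm, fs = NULL, spike_times = NULL,
                               spike_threshold = -20, pre = 0.001,
                               cap = 0.010, return_tol = 1) {
  if (inherits(vm, "vm_trace")) {
    fs <- vm$fs
    vm <- vm$vm
  }
  stopifnot(is.numeric(vm), !is.null(fs))
  n <- length(vm)
  if (is.null(spike_times)) {
    above <- vm >= spike_threshold
    cross <- which(above & !c(FALSE, above[-n]))
    spike_times <- (cross - 1L) / fs
  }
  spans <- list()
  for (ts in spike_times) {
    i0 <- max(1L, round((ts - pre) * fs) + 1L)
    ic <- min(n, round(ts * fs) + 1L)       # threshold-crossing sample
    imax <- min(n, round((ts + cap) * fs) + 1L)
    level <- vm[i0]
    j <- if (ic < imax) {
      ic + which(vm[(ic + 1L):imax] <= level + return_tol)[1L]
    } else {
      NA_integer_
    }
    if (is.na(j)) j <- imax
    spans[[length(spans) + 1L]] <- c(i0, j)
  }
  if (length(spans)) {
    # merge overlapping spans
    spans <- spans[order(vapply(spans, `[[`, numeric(1L), 1L))]
    merged <- list(spans[[1L]])
    for (s in spans[-1L]) {
      last <- merged[[length(merged)]]
      if (s[1L] <= last[2L]) {
        merged[[length(merged)]] <- c(last[1L], max(last[2L], s[2L]))
      } else {
        merged[[length(merged) + 1L]] <- s
      }
    }
    for (s in merged) {
      i0 <- s[1L]
      j <- s[2L]
      if (j > i0) {
        vm[i0:j] <- seq(vm[i0], vm[j], length.out = j - i0 + 1L)
      }
    }
    spans <- lapply(merged, function(s) (s - 1L) / fs)
  }
  structure(list(vm = vm, times = (seq_len(n) - 1L) / fs, fs = fs,
                 interpolated_spans = spans),
            class = "subthreshold_trace")
}

#' Continuous Morlet wavelet transform
#'
#' Magnitude scalogram of a (subthreshold) trace on a 1 Hz pseudo-frequency
#' grid, using the analytic Morlet wavelet with center-frequency parameter
#' 6 (pseudo-frequency f relates to scale s by `f = 6 / (2 pi s)`).
#' Computed per frequency via FFT convolution.
#'
#' @param trace A `subthreshold_trace`, `vm_trace`, or numeric vector.
#' @param fs Sampling rate (Hz); taken from the object if given.
#' @param freqs Frequency grid (Hz), default 10-150 Hz in 1 Hz steps.
#' @param omega0 Morlet center-frequency parameter.
#' @return Object of class `scalogram`: `mag` (freq x time), `freqs`,
#'   `times`, `fs`.
#' @export
morlet_cwt <- function(trace, fs = NULL, freqs = 10:150, omega0 = 6) {
  if (inherits(trace, "subthreshold_trace") || inherits(trace, "vm_trace")) {
    fs <- trace$fs
    trace <- trace$vm
  }
  stopifnot(is.numeric(trace), !is.null(fs), all(freqs > 0),
            all(freqs < fs / 2))
  x <- trace - mean(trace)
  n <- length(x)
  nfft <- stats::nextn(n, 2L)
  X <- stats::fft(c(x, numeric(nfft - n)))
  k <- 0:(nfft - 1L)
  omega <- 2 * pi * ifelse(k <= nfft / 2, k, k - nfft) * fs / nfft
  mag <- matrix(0, nrow = length(freqs), ncol = n)
  for (i in seq_along(freqs)) {
    s <- omega0 / (2 * pi * freqs[i])
    # analytic Morlet, L2-normalized in the frequency domain
    psi_hat <- sqrt(2 * pi * s * fs) * pi^(-0.25) *
      exp(-0.5 * (s * omega - omega0)^2) * (omega > 0)
    w <- stats::fft(X * psi_hat, inverse = TRUE) / nfft
    mag[i, ] <- Mod(w[1:n])
  }
  structure(list(mag = mag, freqs = as.numeric(freqs),
                 times = (seq_len(n) - 1L) / fs, fs = fs),
            class = "scalogram")
}

#' @export
print.scalogram <- function(x, ...) {
  cat(sprintf("<scalogram> %d freqs (%g-%g Hz) x %d samples @ %g Hz\n",
              length(x$freqs), min(x$freqs), max(x$freqs), length(x$times),
              x$fs))
  invisible(x)
}

#' Fit a fixed-frequency sinusoid to a membrane-potential segment
#'
#' The recipe fixes amplitude to the segment standard deviation, offset to
#' the segment mean, and frequency to the ridge maximum, leaving only phase
#' free; the phase of `offset + A cos(2 pi f t + phi)` minimizing the sum
#' of squared errors has the closed form `phi = atan2(-S, C)` with
#' `C = sum(v~ cos)`, `S = sum(v~ sin)`. Note that for a pure sinusoid of
#' amplitude A0 the fitted amplitude is `A0/sqrt(2)` (the SD of a
#' sinusoid), a systematic of the recipe.
#'
#' @param segment Numeric voltage segment (mV).
#' @param fs Sampling rate (Hz).
#' @param frequency Fixed sinusoid frequency (Hz).
#' @param t0 Absolute time (s) of the first sample (phase is reported in
#'   this time base, cosine convention: 0 at a peak).
#' @return List of class `sto_fit`: `phase` (rad, in (-pi, pi]), `amplitude`
#'   (mV), `offset` (mV), `frequency`, `r2`, `t0`.
#' @export
fit_sto_sinusoid <- function(segment, fs, frequency, t0 = 0) {
  stopifnot(length(segment) >= 4L, frequency > 0)
  amp <- stats::sd(segment)
  if (amp == 0) stop("zero-variance segment")
  offset <- mean(segment)
  t <- t0 + (seq_along(segment) - 1L) / fs
  theta <- 2 * pi * frequency * t
  vt <- segment - offset
  C <- sum(vt * cos(theta))
  S <- sum(vt * sin(theta))
  phase <- atan2(-S, C)
  model <- offset + amp * cos(theta + phase)
  sse <- sum((segment - model)^2)
  sst <- sum(vt^2)
  structure(list(phase = phase, amplitude = amp, offset = offset,
                 frequency = frequency, r2 = 1 - sse / sst, t0 = t0),
            class = "sto_fit")
}

#' Detect subthreshold oscillations in a scalogram
#'
#' Iterative ridge extraction under a relaxed magnitude threshold (a low
#' percentile of the band-limited scalogram, permissive enough to capture
#' every plausible oscillation): the global scalogram maximum seeds a ridge
#' that extends bidirectionally, per time step following the magnitude
#' maximum within the continuity limit (<= 30 Hz/ms); the candidate STO is
#' the contiguous stretch around the maximum over which the ridge stays
#' supra-threshold and its instantaneous frequency stays within 20% of the
#' maximum frequency. Candidates shorter than 2 periods are rejected; the
#' rest are confirmed when the fixed-frequency sinusoid fit reaches the
#' `r2_gate` (an automated stand-in for post-hoc visual confirmation).
#' Confirmed epochs are removed; rejected candidates suppress their
#' frequency neighborhood over their epoch (the automated analogue of
#' iterating with refined frequency bounds), and extraction repeats, so at
#' most one confirmed STO occupies any temporal epoch (overlaps resolve to
#' the larger ridge maximum, which is extracted first).
#'
#' @param scalogram A `scalogram` from [morlet_cwt()].
#' @param vm The trace the scalogram came from (`subthreshold_trace` or
#'   numeric), used for the sinusoid fits.
#' @param continuity Frequency-slew limit (Hz/ms).
#' @param band Length-2 search band (Hz).
#' @param min_periods Minimum candidate duration in oscillation periods.
#' @param max_freq_dev Allowed fractional deviation of instantaneous
#'   frequency from the ridge maximum.
#' @param r2_gate Fit-quality gate for confirmation.
#' @param relaxed_percentile Percentile of band-limited scalogram magnitude
#'   used as the relaxed candidate threshold.
#' @param max_events Iteration cap.
#' @return List of class `sto_events`: confirmed events, each a list with
#'   `t_start`, `t_end`, `frequency` (Hz), `n_periods`, `phase`,
#'   `amplitude`, `offset`, `r2`; rejected candidates are tallied in
#'   attribute `"n_rejected"`.
#' @export
detect_stos <- function(scalogram, vm, continuity = 30, band = c(10, 150),
                        min_periods = 2, max_freq_dev = 0.20,
                        r2_gate = 0.40, relaxed_percentile = 90,
                        max_events = 60L) {
  stopifnot(inherits(scalogram, "scalogram"))
  if (inherits(vm, "subthreshold_trace")) vm <- vm$vm
  fsel <- which(scalogram$freqs >= band[1L] & scalogram$freqs <= band[2L])
  M <- scalogram$mag[fsel, , drop = FALSE]
  fr <- scalogram$freqs[fsel]
  fs <- scalogram$fs
  nt <- ncol(M)
  dt_ms <- 1000 / fs
  max_df <- continuity * dt_ms
  # `claimed` marks temporal epochs of *confirmed* STOs (at most one per
  # epoch); `avail` marks time-frequency bins not yet tried as ridge
  # members, so rejected candidates suppress their own ridge without
  # blocking the epoch for refined frequency bounds.
  claimed <- rep(FALSE, nt)
  avail <- matrix(TRUE, nrow = length(fr), ncol = nt)
  thr_mag <- stats::quantile(M, relaxed_percentile / 100)
  events <- list()
  n_rejected <- 0L
  for (iter in seq_len(max_events)) {
    srch <- avail
    srch[, claimed] <- FALSE
    if (!any(srch)) break
    im <- arrayInd(which.max(ifelse(srch, M, -Inf)), dim(M))
    j0 <- im[1L]
    k0 <- im[2L]
    if (M[j0, k0] <= 0) break
    # trace the ridge outward from the seed through unclaimed columns
    fidx <- integer(nt)
    fidx[k0] <- j0
    for (dir in c(1L, -1L)) {
      k <- k0
      while ((k + dir) >= 1L && (k + dir) <= nt && !claimed[k + dir]) {
        jr <- which(abs(fr - fr[fidx[k]]) <= max_df)
        jn <- jr[which.max(M[jr, k + dir])]
        fidx[k + dir] <- jn
        k <- k + dir
      }
    }
    cols <- which(fidx > 0L)
    f_max <- fr[j0]
    # contiguous supra-threshold stretch around the maximum within the
    # frequency tolerance
    within <- abs(fr[fidx[cols]] - f_max) / f_max < max_freq_dev &
      M[cbind(fidx[cols], cols)] >= thr_mag
    pos0 <- match(k0, cols)
    lo <- pos0
    while (lo > 1L && within[lo - 1L] && cols[lo - 1L] == cols[lo] - 1L) {
      lo <- lo - 1L
    }
    hi <- pos0
    while (hi < length(cols) && within[hi + 1L] &&
           cols[hi + 1L] == cols[hi] + 1L) {
      hi <- hi + 1L
    }
    span <- cols[lo:hi]
    reject <- function() {
      # refine frequency bounds: suppress the candidate's frequency
      # neighborhood over its epoch (at least a minimum-duration window
      # around the seed, so degenerate candidates cannot stall the search)
      rows_sup <- which(abs(fr - f_max) / f_max < max_freq_dev)
      half_win <- ceiling(min_periods / f_max * fs / 2)
      sup_cols <- max(1L, k0 - half_win):min(nt, k0 + half_win)
      avail[rows_sup, sup_cols] <<- FALSE
      n_rejected <<- n_rejected + 1L
    }
    dur <- length(span) / fs
    if (dur * f_max < min_periods) {
      reject()
      next
    }
    seg <- vm[span]
    t0 <- (span[1L] - 1L) / fs
    fit <- tryCatch(fit_sto_sinusoid(seg, fs, f_max, t0 = t0),
                    error = function(e) NULL)
    if (is.null(fit) || fit$r2 < r2_gate) {
      reject()
      next
    }
    claimed[span] <- TRUE
    events[[length(events) + 1L]] <- list(
      t_start = t0, t_end = (span[length(span)] - 1L) / fs,
      frequency = f_max, n_periods = dur * f_max,
      phase = fit$phase, amplitude = fit$amplitude, offset = fit$offset,
      r2 = fit$r2)
  }
  if (length(events) > 1L) {
    events <- events[order(vapply(events, `[[`, numeric(1L), "t_start"))]
  }
  structure(list(events = events, band = band, r2_gate = r2_gate),
            class = "sto_events", n_rejected = n_rejected)
}

#' @export
print.sto_events <- function(x, ...) {
  cat(sprintf("<sto_events> %d confirmed STO(s)\n", length(x$events)))
  for (e in x$events) {
    cat(sprintf("  %.3f-%.3f s, %.0f Hz, %.1f periods, r2=%.2f\n",
                e$t_start, e$t_end, e$frequency, e$n_periods, e$r2))
  }
  invisible(x)
}

#' Classify a cell as resonant
#'
#' A cell is resonant iff it exhibits at least `threshold` confirmed STO
#' events in total across the step-current protocol (10 steps, 50-500 pA in
#' 50 pA increments, one trial each — hence the default of 10, one event
#' per step on average).
#'
#' @param sto_events A `sto_events` object, a list of them (one per step),
#'   or a bare event count.
#' @param threshold Minimum total confirmed STOs.
#' @return `"resonant"` or `"non-resonant"` (character), with the count in
#'   attribute `"n_stos"`.
#' @export
classify_resonant <- function(sto_events, threshold = 10L) {
  n <- if (is.numeric(sto_events)) {
    as.integer(sto_events)
  } else if (inherits(sto_events, "sto_events")) {
    length(sto_events$events)
  } else {
    sum(vapply(sto_events, function(e) {
      if (inherits(e, "sto_events")) length(e$events) else as.integer(e)
    }, integer(1L)))
  }
  structure(if (n >= threshold) "resonant" else "non-resonant", n_stos = n)
}

#' Spike phases and rates relative to preceding STOs
#'
#' Relates spikes to the immediately preceding STO: spikes within two STO
#' periods after the STO end are assigned a phase extrapolated from the
#' sinusoid fit (cosine convention, 0 = STO peak, reported in (-pi, pi];
#' the reference is the last fitted peak inside the STO), and their
#' instantaneous rates (sequential 1/ISI, the interval ending at each
#' qualifying spike) are paired with the STO frequency. A mean
#' rate:frequency ratio of 1 indicates one spike per oscillation period;
#' firing on every other period halves it.
#'
#' @param sto_events A `sto_events` object.
#' @param spike_times Spike times (s), same time base as the STO events.
#' @return List of class `sto_spike_metrics`: `phases` (rad), `ratio_samples`
#'   (data frame `rate`, `sto_freq`, `ratio`), `mean_ratio`.
#' @export
sto_spike_metrics <- function(sto_events, spike_times) {
  stopifnot(inherits(sto_events, "sto_events"))
  if (!length(sto_events$events)) stop("at least one STO is required")
  spike_times <- sort(spike_times)
  phases <- numeric(0L)
  rows <- list()
  for (e in sto_events$events) {
    f <- e$frequency
    sel <- which(spike_times > e$t_end & spike_times <= e$t_end + 2 / f)
    if (!length(sel)) next
    sp <- spike_times[sel]
    # peaks of cos(2 pi f t + phase) at t = (2 pi k - phase) / (2 pi f);
    # t_ref = last peak at or before t_end
    k_last <- floor((2 * pi * f * e$t_end + e$phase) / (2 * pi))
    t_ref <- (2 * pi * k_last - e$phase) / (2 * pi * f)
    ph <- (2 * pi * f * (sp - t_ref)) %% (2 * pi)
    ph <- ifelse(ph > pi, ph - 2 * pi, ph)   # map to (-pi, pi]
    phases <- c(phases, ph)
    # sequential rate of each qualifying spike: inverse interval to the
    # spike preceding it in the full train
    prev_ok <- sel[sel > 1L]
    if (length(prev_ok)) {
      rates <- 1 / (spike_times[prev_ok] - spike_times[prev_ok - 1L])
      rows[[length(rows) + 1L]] <- data.frame(rate = rates, sto_freq = f,
                                              ratio = rates / f)
    }
  }
  ratio_samples <- if (length(rows)) do.call(rbind, rows) else
    data.frame(rate = numeric(0L), sto_freq = numeric(0L),
               ratio = numeric(0L))
  structure(list(phases = phases, ratio_samples = ratio_samples,
                 mean_ratio = if (nrow(ratio_samples))
                   mean(ratio_samples$ratio) else NA_real_),
            class = "sto_spike_metrics")
}
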