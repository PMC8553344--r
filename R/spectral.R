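# Welch cross-spectrogram of two lists of per-trial signals (workhorse).
# One tapered segment per time bin (the window is both the Welch segment and
# the time-resolution unit); power is |S12| with the standard Welch scaling
# 1/(fs * sum(w^2)), so the auto case equals the textbook PSD estimate.
.welch_spectrogram <- function(sigs_a, sigs_b, fs, window, overlap, t_ref) {
  nwin <- round(window * fs)
  hop <- max(1L, round(nwin * (1 - overlap)))
  n <- length(sigs_a[[1L]])
  if (nwin > n) stop("window longer than record")
  starts <- seq(1L, n - nwin + 1L, by = hop)
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(nwin) - 1L) / (nwin - 1L))
  scale <- 1 / (fs * sum(w^2))
  nf <- floor(nwin / 2) + 1L
  pow <- matrix(0, nrow = nf, ncol = length(starts))
  n_trials <- length(sigs_a)
  for (tn in seq_len(n_trials)) {
    a <- sigs_a[[tn]]
    b <- sigs_b[[tn]]
    for (k in seq_along(starts)) {
      seg <- starts[k]:(starts[k] + nwin - 1L)
      A <- stats::fft(w * a[seg])[1:nf]
      B <- if (identical(a, b)) A else stats::fft(w * b[seg])[1:nf]
      pow[, k] <- pow[, k] + Mod(A * Conj(B)) * scale
    }
  }
  pow <- pow / n_trials
  structure(list(times = (starts - 1L + nwin / 2) / fs - t_ref,
                 freqs = (0:(nf - 1L)) * fs / nwin,
                 power = pow, n_trials = n_trials,
                 window = window, hop = hop / fs, fs = fs),
            class = "spectrogram")
}

#' Cross-power spectral density spectrogram of a pair
#'
#' Welch cross-spectra (100 ms Hamming window, 95% overlap by default) of
#' Gaussian-convolved, mean-subtracted event trains, with per-window
#' cross-spectral magnitude averaged across trials. High values at a
#' time-frequency bin indicate periodic spike-time synchrony at that
#' frequency around that time. Frequency resolution at defaults is
#' 1/window = 10 Hz; the time step is the 5 ms hop.
#'
#' @param pair A [pair_recording()].
#' @param window Welch segment length (s). Use 0.5 s for theta-band (2-12 Hz)
#'   analyses, which 100 ms segments cannot resolve.
#' @param overlap Fractional window overlap.
#' @param fs,sigma Convolution sampling rate (Hz) and kernel SD (s).
#' @param t_ref Time origin (s) of the output time axis; defaults to the
#'   first stimulus onset of the attached protocol, else 0.
#' @return Object of class `spectrogram`: `times` (window centers, s,
#'   relative to `t_ref`), `freqs` (Hz), `power` (freq x time, nonnegative),
#'   `kind`, `n_trials`, `hop`.
#' @export
cpsd_spectrogram <- function(pair, window = 0.100, overlap = 0.95,
                             fs = 10000, sigma = 0.001, t_ref = NULL) {
  stopifnot(inherits(pair, "pair_recording"))
  if (is.null(t_ref)) {
    pr <- pair$cell_a$protocol
    t_ref <- if (!is.null(pr)) pr$stim_onsets[1L] else 0
  }
  conv <- function(ts) {
    lapply(ts$trains, function(tr) {
      convolve_events(tr, fs, sigma, mean_subtract = TRUE)$samples
    })
  }
  sg <- .welch_spectrogram(conv(pair$cell_a), conv(pair$cell_b), fs,
                           window, overlap, t_ref)
  sg$kind <- "CPSD"
  sg
}

#' Auto-power spectral density spectrogram of a single cell
#'
#' The power spectrum of the auto-correlogram: [cpsd_spectrogram()] of a
#' cell with itself. Periodic firing appears as supra-threshold gamma-band
#' structure; a Poisson train concentrates power in sub-gamma frequencies.
#'
#' @param trials A [trial_set()].
#' @inheritParams cpsd_spectrogram
#' @return A `spectrogram` with `kind = "APSD"`.
#' @export
apsd_spectrogram <- function(trials, window = 0.100, overlap = 0.95,
                             fs = 10000, sigma = 0.001, t_ref = NULL) {
  stopifnot(inherits(trials, "trial_set"))
  if (is.null(t_ref)) {
    t_ref <- if (!is.null(trials$protocol)) trials$protocol$stim_onsets[1L]
             else 0
  }
  sigs <- lapply(trials$trains, function(tr) {
    convolve_events(tr, fs, sigma, mean_subtract = TRUE)$samples
  })
  sg <- .welch_spectrogram(sigs, sigs, fs, window, overlap, t_ref)
  sg$kind <- "APSD"
  sg
}

#' Spectrogram of raw sampled traces
#'
#' The same Welch machinery applied to mean-subtracted raw current or
#' voltage traces in place of convolved event trains (e.g. to ask whether
#' synaptic input itself carries gamma-frequency patterning).
#'
#' @param traces_a,traces_b Lists (one element per trial) of equal-length
#'   numeric signals; omit `traces_b` for an auto-spectrogram.
#' @param fs Sampling rate (Hz).
#' @inheritParams cpsd_spectrogram
#' @return A `spectrogram`.
#' @export
signal_spectrogram <- function(traces_a, traces_b = NULL, fs,
                               window = 0.100, overlap = 0.95, t_ref = 0) {
  dm <- function(xs) lapply(xs, function(x) x - mean(x))
  a <- dm(traces_a)
  b <- if (is.null(traces_b)) a else dm(traces_b)
  sg <- .welch_spectrogram(a, b, fs, window, overlap, t_ref)
  sg$kind <- if (is.null(traces_b)) "APSD" else "CPSD"
  sg
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf(
    "<spectrogram> %s: %d freqs (%g-%g Hz) x %d times (%.3f-%.3f s), %d trials\n",
    x$kind, length(x$freqs), min(x$freqs), max(x$freqs), length(x$times),
    min(x$times), max(x$times), x$n_trials))
  invisible(x)
}

#' Band- and time-averaged spectrogram power
#'
#' Mean power over an inclusive frequency band and (optionally) a time
#' window, e.g. 2-12 Hz across the whole protocol for theta-band synchrony
#' or 40-150 Hz for overall firing periodicity.
#'
#' @param sg A `spectrogram`.
#' @param f_lo,f_hi Band edges (Hz), inclusive.
#' @param t_window Optional length-2 time interval (s, spectrogram time
#'   base); defaults to all times.
#' @return Scalar mean power.
#' @export
band_average <- function(sg, f_lo, f_hi, t_window = NULL) {
  stopifnot(inherits(sg, "spectrogram"))
  fsel <- sg$freqs >= f_lo & sg$freqs <= f_hi
  if (!any(fsel)) stop("band does not intersect the frequency grid")
  tsel <- if (is.null(t_window)) rep(TRUE, length(sg$times)) else
    sg$times >= t_window[1L] & sg$times <= t_window[2L]
  if (!any(tsel)) stop("time window does not intersect the time grid")
  mean(sg$power[fsel, tsel, drop = FALSE])
}

#' Average a spectrogram across stimulation cycles
#'
#' Folds the time axis modulo the protocol's cycle period (time 0 = a pulse
#' onset) and averages aligned bins, yielding a one-cycle spectrogram of the
#' average stimulation cycle.
#'
#' @param sg A `spectrogram` whose time axis is relative to the first pulse
#'   onset.
#' @param protocol A [protocol_config()].
#' @return A `spectrogram` whose times span `[0, cycle_period)`.
#' @export
cycle_average <- function(sg, protocol) {
  stopifnot(inherits(sg, "spectrogram"), inherits(protocol, "protocol_config"))
  period <- protocol$cycle_period
  nbin <- round(period / sg$hop)
  if (abs(nbin * sg$hop - period) > 1e-9) {
    stop("cycle period must be a multiple of the spectrogram hop")
  }
  n_cycles <- protocol$n_pulses
  sel <- which(sg$times >= -1e-9 & sg$times < n_cycles * period - 1e-9)
  if (length(sel) < 2L * nbin) stop("need at least 2 complete cycles")
  # keep only whole cycles
  n_complete <- floor(length(sel) / nbin)
  if (n_complete < 2L) stop("need at least 2 complete cycles")
  sel <- sel[seq_len(n_complete * nbin)]
  phase <- (round(sg$times[sel] / sg$hop) %% nbin)
  pow <- matrix(0, nrow = nrow(sg$power), ncol = nbin)
  cnt <- integer(nbin)
  for (k in seq_along(sel)) {
    j <- phase[k] + 1L
    pow[, j] <- pow[, j] + sg$power[, sel[k]]
    cnt[j] <- cnt[j] + 1L
  }
  sg$power <- sweep(pow, 2L, cnt, "/")
  sg$times <- (0:(nbin - 1L)) * sg$hop
  sg$n_cycles <- n_complete
  sg
}

#' Export a spectrogram as a delimited matrix
#'
#' First row holds window-center times, first column frequencies.
#'
#' @param sg A `spectrogram`.
#' @param path Output path.
#' @param sep Field separator.
#' @export
write_spectrogram <- function(sg, path, sep = "\t") {
  m <- cbind(freq_hz = sg$freqs, sg$power)
  colnames(m) <- c("freq_hz", sprintf("t%.4f", sg$times))
  utils::write.table(m, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
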