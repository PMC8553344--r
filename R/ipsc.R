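# Rolling sums over windows of length N starting at each sample
# (value k corresponds to the window starting at sample k).
.roll_start <- function(x, N) {
  cs <- cumsum(c(0, x))
  n <- length(x) - N + 1L
  cs[(N + 1L):(N + n)] - cs[1:n]
}

#' Template-matching IPSC detection (Clements-Bekkers)
#'
#' Slides a scaled biexponential template along an outward-positive current
#' trace, at each offset fitting scale and offset by least squares. The
#' detection criterion is scale / standard error of the fit; candidate
#' events are local criterion maxima where the criterion exceeds
#' `criterion_threshold` and the fitted amplitude exceeds 2.5x the baseline
#' noise SD. Events closer than the template's `min_separation` are merged,
#' keeping the larger criterion.
#'
#' @param trace Numeric current trace (pA, outward-positive) or an
#'   [ipsc_trace()] object.
#' @param fs Sampling rate (Hz, >= 5 kHz); taken from the object if given.
#' @param template An [ipsc_template()].
#' @param criterion_threshold Detection-criterion cutoff (the amplitude rule
#'   is applied in conjunction).
#' @param baseline_window Length-2 interval (s) of event-free baseline used
#'   for the noise SD; required.
#' @param amplitude_sd_mult Amplitude threshold in baseline-noise SDs.
#' @return Data frame of class `ipsc_events`: `time` (s, onset of the rising
#'   phase), `amplitude` (pA, fitted scale), `criterion`; attributes
#'   `noise_sd`, `fs`, `template`.
#' @export
detect_ipscs <- function(trace, fs = NULL, template = ipsc_template(),
                         criterion_threshold = 3,
                         baseline_window = NULL,
                         amplitude_sd_mult = 2.5) {
  if (inherits(trace, "ipsc_trace")) {
    fs <- trace$fs
    trace <- trace$current
  }
  stopifnot(is.numeric(trace), !is.null(fs), fs >= 5000)
  if (is.null(baseline_window)) {
    stop("a baseline segment must be designated for the noise SD")
  }
  tmplv <- .template_vector(template, fs)
  N <- length(tmplv)
  if (length(trace) < N) stop("trace shorter than the template")
  bsel <- which((seq_along(trace) - 1L) / fs >= baseline_window[1L] &
                (seq_along(trace) - 1L) / fs < baseline_window[2L])
  if (length(bsel) < 2L) stop("baseline window contains too few samples")
  noise_sd <- stats::sd(trace[bsel])
  ST <- sum(tmplv)
  STT <- sum(tmplv^2)
  denom <- STT - ST^2 / N
  SD1 <- .roll_start(trace, N)
  SDD <- .roll_start(trace^2, N)
  # sliding sum(template * data): filter() convolution, aligned to starts
  conv <- stats::filter(trace, rev(tmplv), method = "convolution",
                        sides = 1L)
  STD <- as.numeric(conv[N:length(trace)])
  scale <- (STD - ST * SD1 / N) / denom
  offset <- (SD1 - scale * ST) / N
  SSE <- SDD + scale^2 * STT + N * offset^2 -
    2 * scale * STD - 2 * offset * SD1 + 2 * scale * offset * ST
  SSE[SSE < 0] <- 0
  se <- sqrt(SSE / (N - 1L))
  crit <- ifelse(se > 0, scale / se, 0)
  ok <- crit > criterion_threshold & scale >= amplitude_sd_mult * noise_sd
  n <- length(crit)
  locmax <- c(FALSE, crit[2:(n - 1L)] > crit[1:(n - 2L)] &
                     crit[2:(n - 1L)] >= crit[3:n], FALSE)
  cand <- which(ok & locmax)
  # merge events closer than min_separation, keeping the larger criterion
  if (length(cand) > 1L) {
    min_sep <- round(template$min_separation * fs)
    keep <- logical(length(cand))
    ord <- order(crit[cand], decreasing = TRUE)
    taken <- integer(0L)
    for (i in ord) {
      if (!length(taken) || all(abs(cand[i] - taken) >= min_sep)) {
        keep[i] <- TRUE
        taken <- c(taken, cand[i])
      }
    }
    cand <- sort(cand[keep])
  }
  out <- data.frame(
    time = (cand - 1L) / fs + template$baseline,
    amplitude = scale[cand],
    criterion = crit[cand])
  attr(out, "noise_sd") <- noise_sd
  attr(out, "fs") <- fs
  attr(out, "template") <- template
  class(out) <- c("ipsc_events", "data.frame")
  out
}

#' IPSC kinetics: 20-80% rise times and median-waveform decay constant
#'
#' Rise times are measured per event from the local pre-onset baseline to
#' the post-onset peak, with linear interpolation between samples at the 20%
#' and 80% crossings. Because decay constants of individual events are
#' unreliable during barrages, the decay constant is estimated once per cell
#' by a single-exponential least-squares fit to the peak-aligned median
#' waveform across all detected events (requires >= 5 events). The fit
#' starts `decay_delay` after the peak so the residual rise term (which
#' slows the apparent decay just after the peak) does not bias tau.
#'
#' @param events An `ipsc_events` data frame from [detect_ipscs()].
#' @param trace The current trace the events were detected in (numeric or
#'   [ipsc_trace()]).
#' @param fs Sampling rate (Hz); taken from `events` if absent.
#' @param peak_search Time after onset searched for the peak (s).
#' @param decay_span Post-peak span fitted for the decay (s).
#' @param decay_delay Post-peak delay before the decay fit starts (s).
#' @return List of class `ipsc_kinetics`: `rise_20_80_ms` (per event, NA
#'   where undefined), `tau_decay_ms` (NA with `decay_defined = FALSE` when
#'   < 5 events or the fit fails), `median_waveform`.
#' @export
ipsc_kinetics <- function(events, trace, fs = NULL, peak_search = 0.003,
                          decay_span = 0.006, decay_delay = 0.001) {
  if (inherits(trace, "ipsc_trace")) {
    if (is.null(fs)) fs <- trace$fs
    trace <- trace$current
  }
  if (is.null(fs)) fs <- attr(events, "fs")
  stopifnot(nrow(events) >= 1L, !is.null(fs))
  npk <- round(peak_search * fs)
  nbl <- max(1L, round(0.0005 * fs))
  rise <- rep(NA_real_, nrow(events))
  for (i in seq_len(nrow(events))) {
    i0 <- round(events$time[i] * fs) + 1L
    if (i0 - nbl < 1L || i0 + npk > length(trace)) next
    base <- mean(trace[(i0 - nbl):(i0 - 1L)])
    seg <- trace[i0:(i0 + npk)] - base
    ipk <- which.max(seg)
    amp <- seg[ipk]
    if (amp <= 0) next
    cross <- function(level) {
      j <- which(seg[1:ipk] >= level)[1L]
      if (is.na(j)) return(NA_real_)
      if (j == 1L) return(0)
      # linear interpolation between samples j-1 and j
      frac <- (level - seg[j - 1L]) / (seg[j] - seg[j - 1L])
      (j - 2L + frac) / fs
    }
    t20 <- cross(0.2 * amp)
    t80 <- cross(0.8 * amp)
    if (!is.na(t20) && !is.na(t80)) rise[i] <- (t80 - t20) * 1000
  }
  tau <- NA_real_
  med <- NULL
  decay_defined <- FALSE
  if (nrow(events) >= 5L) {
    ndec <- round(decay_span * fs)
    segs <- matrix(NA_real_, nrow = nrow(events), ncol = npk + ndec + 1L)
    for (i in seq_len(nrow(events))) {
      i0 <- round(events$time[i] * fs) + 1L
      if (i0 - nbl < 1L || i0 + npk > length(trace)) next
      base <- mean(trace[(i0 - nbl):(i0 - 1L)])
      ipk <- i0 - 1L + which.max(trace[i0:(i0 + npk)] - base)
      idx <- (ipk - npk):(ipk + ndec)
      if (idx[1L] < 1L || idx[length(idx)] > length(trace)) next
      segs[i, ] <- trace[idx] - base
    }
    if (sum(stats::complete.cases(segs)) >= 5L) {
      med <- apply(segs[stats::complete.cases(segs), , drop = FALSE], 2L,
                   stats::median)
      ndel <- round(decay_delay * fs)
      dec <- med[(npk + 1L + ndel):length(med)]    # from peak + delay onward
      tt <- (seq_along(dec) - 1L) / fs
      pos <- dec > 0
      if (sum(pos) >= 3L) {
        # log-linear start values, then nonlinear refinement
        cf <- stats::lm(log(dec[pos]) ~ tt[pos])$coefficients
        tau0 <- -1 / cf[2L]
        fit <- tryCatch(
          stats::nls(dec ~ A * exp(-tt / tau_s),
                     start = list(A = dec[1L],
                                  tau_s = max(min(tau0, 0.02), 1e-4)),
                     control = stats::nls.control(warnOnly = TRUE)),
          error = function(e) NULL)
        if (!is.null(fit)) {
          tau <- stats::coef(fit)[["tau_s"]] * 1000
          decay_defined <- is.finite(tau) && tau > 0
        }
      }
    }
  }
  structure(list(rise_20_80_ms = rise, tau_decay_ms = tau,
                 decay_defined = decay_defined, median_waveform = med),
            class = "ipsc_kinetics")
}

#' Synchronous/asynchronous decomposition of paired event lists
#'
#' An event is synchronous iff a partner event in the other cell lies within
#' +/- `w` of it; each event is classified independently, which makes the
#' classification symmetric under swapping the pair. Within each class,
#' time-resolved rates are the sequential inverse inter-event intervals.
#'
#' @param a,b Event lists for the two cells: numeric time vectors or data
#'   frames with columns `time` and optionally `amplitude`.
#' @param w Synchrony half-window (s); the 1 ms default defines the
#'   synchronous-IPSC window.
#' @param stim_window Optional length-2 interval (s) restricting analysis to
#'   evoked events.
#' @return List of class `sync_decomposition`: per-cell data frames (`a`,
#'   `b`) with `time`, `amplitude`, `synchronous`; class-wise rate series;
#'   `f_synch` (pooled synchronous fraction); `rate_ratio` and
#'   `amplitude_ratio` (synchronous / asynchronous).
#' @export
synchrony_decomposition <- function(a, b, w = 0.001, stim_window = NULL) {
  norm <- function(x) {
    if (is.data.frame(x)) {
      data.frame(time = x$time,
                 amplitude = if ("amplitude" %in% names(x)) x$amplitude
                             else NA_real_)
    } else {
      data.frame(time = as.numeric(x), amplitude = NA_real_)
    }
  }
  a <- norm(a)
  b <- norm(b)
  if (!is.null(stim_window)) {
    a <- a[a$time >= stim_window[1L] & a$time <= stim_window[2L], ,
           drop = FALSE]
    b <- b[b$time >= stim_window[1L] & b$time <= stim_window[2L], ,
           drop = FALSE]
  }
  has_partner <- function(x, other) {
    if (!nrow(x)) return(logical(0L))
    if (!nrow(other)) return(rep(FALSE, nrow(x)))
    ot <- sort(other$time)
    idx <- findInterval(x$time, ot)
    lo <- pmax(idx, 1L)
    hi <- pmin(idx + 1L, length(ot))
    pmin(abs(x$time - ot[lo]), abs(x$time - ot[hi])) <= w + 1e-12
  }
  a$synchronous <- has_partner(a, b)
  b$synchronous <- has_partner(b, a)
  class_rates <- function(x) {
    cls <- factor(ifelse(x$synchronous, "synchronous", "asynchronous"),
                  levels = c("synchronous", "asynchronous"))
    lapply(split(x$time, cls), function(tt) {
      if (length(tt) < 2L) {
        data.frame(time = numeric(0L), rate = numeric(0L))
      } else {
        data.frame(time = tt[-1L], rate = 1 / diff(tt))
      }
    })
  }
  n_sync <- sum(a$synchronous) + sum(b$synchronous)
  n_tot <- nrow(a) + nrow(b)
  mean_rate <- function(lst, cls) {
    rr <- c(if (!is.null(lst$a[[cls]])) lst$a[[cls]]$rate,
            if (!is.null(lst$b[[cls]])) lst$b[[cls]]$rate)
    if (length(rr)) mean(rr) else NA_real_
  }
  rates <- list(a = class_rates(a), b = class_rates(b))
  amp_mean <- function(df, cls) {
    v <- df$amplitude[df$synchronous == cls]
    if (all(is.na(v)) || !length(v)) NA_real_ else mean(v, na.rm = TRUE)
  }
  amp_sync <- mean(c(amp_mean(a, TRUE), amp_mean(b, TRUE)), na.rm = TRUE)
  amp_async <- mean(c(amp_mean(a, FALSE), amp_mean(b, FALSE)), na.rm = TRUE)
  structure(list(
    a = a, b = b, rates = rates, w = w,
    f_synch = if (n_tot) n_sync / n_tot else NA_real_,
    rate_ratio = mean_rate(rates, "synchronous") /
      mean_rate(rates, "asynchronous"),
    amplitude_ratio = amp_sync / amp_async),
    class = "sync_decomposition")
}

#' Synchronous-fraction curve over synchrony windows
#'
#' F_synch(w): the fraction of events classified synchronous under
#' [synchrony_decomposition()] at each half-window of the grid. Monotone
#' non-decreasing in w by set inclusion. For independent Poisson trains of
#' rate r the expectation is `1 - exp(-2 r w)`.
#'
#' @param a,b Event lists (see [synchrony_decomposition()]).
#' @param w_grid Synchrony half-windows (s).
#' @param stim_window Optional evoked-window restriction (s).
#' @return Data frame of class `synchrony_curve`: `w` (s), `f_synch`
#'   (pooled), `f_a`, `f_b` (per cell).
#' @export
f_synch_curve <- function(a, b,
                          w_grid = c(0.5, 1, 2, 3, 4, 5) / 1000,
                          stim_window = NULL) {
  rows <- lapply(w_grid, function(w) {
    d <- synchrony_decomposition(a, b, w = w, stim_window = stim_window)
    data.frame(w = w, f_synch = d$f_synch,
               f_a = if (nrow(d$a)) mean(d$a$synchronous) else NA_real_,
               f_b = if (nrow(d$b)) mean(d$b$synchronous) else NA_real_)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("synchrony_curve", "data.frame")
  out
}

#' Read a sampled trace from delimited text
#'
#' Two columns: time (s) and the sampled quantity (current in pA or
#' voltage in mV); the sampling rate is inferred from the time column.
#'
#' @param path File path.
#' @param sep Field separator.
#' @return List with `samples`, `times`, `fs`.
#' @export
read_trace_table <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep)
  if (ncol(df) < 2L) stop("expected two columns: time and samples")
  dt <- stats::median(diff(df[[1L]]))
  list(samples = df[[2L]], times = df[[1L]], fs = 1 / dt)
}
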