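#' Event train
#'
#' Canonical container for a single trial's timestamped events (spikes or
#' detected synaptic events), in seconds from trial onset.
#'
#' @param times Numeric vector of event times in seconds, will be sorted.
#'   Must lie in `[0, duration]`.
#' @param duration Trial duration in seconds (> 0).
#' @param label Optional cell identifier.
#' @return An object of class `event_train` with fields `times`, `duration`,
#'   `label`.
#' @export
event_train <- function(times, duration, label = NA_character_) {
  times <- as.numeric(times)
  stopifnot(is.numeric(duration), length(duration) == 1L, duration > 0)
  if (anyNA(times)) stop("event times must be finite")
  times <- sort(times)
  if (length(times) && (times[1L] < 0 || times[length(times)] > duration)) {
    stop("event times must lie within [0, duration]")
  }
  if (anyDuplicated(times)) times <- unique(times)
  structure(list(times = times, duration = duration, label = label),
            class = "event_train")
}

#' @export
print.event_train <- function(x, ...) {
  cat(sprintf("<event_train> %d events over %.3f s%s\n", length(x$times),
              x$duration,
              if (!is.na(x$label)) paste0(" [", x$label, "]") else ""))
  invisible(x)
}

#' Photostimulation protocol
#'
#' Describes the repeating light-pulse protocol that paces the recording:
#' by default five 10 ms pulses delivered at a 200 ms inter-pulse interval
#' (5 Hz), the sniff-paced regime the analysis assumes.
#'
#' @param stim_onsets Pulse onset times (s), ascending. Defaults to five
#'   onsets starting at `t_first` spaced by `cycle_period`.
#' @param cycle_period Inter-pulse interval in seconds.
#' @param pulse_width Light-pulse width in seconds.
#' @param n_pulses Number of pulses (used only when `stim_onsets` is NULL).
#' @param t_first Onset of the first pulse (s).
#' @return An object of class `protocol_config`.
#' @export
protocol_config <- function(stim_onsets = NULL, cycle_period = 0.2,
                            pulse_width = 0.010, n_pulses = 5L,
                            t_first = 0.1) {
  stopifnot(cycle_period > pulse_width)
  if (is.null(stim_onsets)) {
    stim_onsets <- t_first + cycle_period * (seq_len(n_pulses) - 1L)
  }
  stim_onsets <- as.numeric(stim_onsets)
  if (is.unsorted(stim_onsets, strictly = TRUE)) {
    stop("stim_onsets must be strictly ascending")
  }
  structure(list(stim_onsets = stim_onsets, cycle_period = cycle_period,
                 pulse_width = pulse_width, n_pulses = length(stim_onsets)),
            class = "protocol_config")
}

#' Trial set
#'
#' A cell's event trains across repeated trials of the same protocol.
#'
#' @param trains List of [event_train()] objects sharing one duration.
#' @param protocol A [protocol_config()] (optional).
#' @return An object of class `trial_set`.
#' @export
trial_set <- function(trains, protocol = NULL) {
  stopifnot(length(trains) >= 1L,
            all(vapply(trains, inherits, logical(1L), "event_train")))
  durs <- vapply(trains, `[[`, numeric(1L), "duration")
  if (diff(range(durs)) > 1e-12) stop("all trials must share one duration")
  structure(list(trains = trains, protocol = protocol,
                 duration = durs[1L], n_trials = length(trains)),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("<trial_set> %d trials x %.3f s, %.1f events/trial\n",
              x$n_trials, x$duration,
              mean(vapply(x$trains, function(tr) length(tr$times),
                          numeric(1L)))))
  invisible(x)
}

#' Paired recording
#'
#' Two simultaneously recorded cells with matching trial structure, plus the
#' cell-type and glomerular metadata the population analyses group by.
#'
#' @param cell_a,cell_b [trial_set()] objects with matching trial counts and
#'   durations.
#' @param cell_types Character vector of length 2, each one of
#'   `"MC"`, `"sTC"`, `"mTC"`, `"dTC"`.
#' @param glomerular_relation `"homotypic"`, `"heterotypic"` or `"unknown"`.
#' @param intersomatic Optional named list (total/lateral distance, depth, um).
#' @param pair_id Optional identifier.
#' @return An object of class `pair_recording`.
#' @export
pair_recording <- function(cell_a, cell_b,
                           cell_types = c("MC", "MC"),
                           glomerular_relation = "unknown",
                           intersomatic = NULL, pair_id = NA_character_) {
  stopifnot(inherits(cell_a, "trial_set"), inherits(cell_b, "trial_set"))
  if (cell_a$n_trials != cell_b$n_trials) {
    stop("trial counts must match between cells")
  }
  if (abs(cell_a$duration - cell_b$duration) > 1e-12) {
    stop("trial durations must match between cells")
  }
  cell_types <- match.arg(cell_types, c("MC", "sTC", "mTC", "dTC"),
                          several.ok = TRUE)
  glomerular_relation <- match.arg(glomerular_relation,
                                   c("homotypic", "heterotypic", "unknown"))
  structure(list(cell_a = cell_a, cell_b = cell_b, cell_types = cell_types,
                 glomerular_relation = glomerular_relation,
                 intersomatic = intersomatic, pair_id = pair_id,
                 n_trials = cell_a$n_trials, duration = cell_a$duration),
            class = "pair_recording")
}

#' @export
print.pair_recording <- function(x, ...) {
  cat(sprintf("<pair_recording> %s-%s (%s), %d trials x %.3f s\n",
              x$cell_types[1L], x$cell_types[2L], x$glomerular_relation,
              x$n_trials, x$duration))
  invisible(x)
}

#' Convolve event times with a Gaussian kernel
#'
#' Replaces each event by a unit-area Gaussian (default 1 ms standard
#' deviation) sampled on a fixed grid, the representation all correlogram and
#' spectral analyses operate on. The kernel is truncated at +/- 5 sigma and
#' not renormalized at the record edges, so events within 5 sigma of an edge
#' lose a little mass; analysis windows should be padded accordingly.
#'
#' @param train An [event_train()].
#' @param fs Sampling rate of the output signal (Hz).
#' @param sigma Kernel standard deviation (s).
#' @param mean_subtract If TRUE (the default used for spectral analysis),
#'   subtract the signal mean.
#' @return An object of class `convolved_train`: `samples` (signal, in 1/s
#'   before mean subtraction), `times`, `fs`, `kernel_sigma`,
#'   `mean_subtracted`.
#' @export
convolve_events <- function(train, fs = 10000, sigma = 0.001,
                            mean_subtract = FALSE) {
  stopifnot(inherits(train, "event_train"), sigma > 0)
  if (fs < 4 / sigma) stop("fs too low to resolve the kernel (need fs >= 4/sigma)")
  n <- round(train$duration * fs)
  x <- numeric(n)
  half <- ceiling(5 * sigma * fs)
  if (length(train$times)) {
    kt <- (-half:half) / fs
    for (ev in train$times) {
      ic <- round(ev * fs) + 1L            # grid point nearest the event
      idx <- (ic - half):(ic + half)
      keep <- idx >= 1L & idx <= n
      tt <- (idx[keep] - 1L) / fs
      x[idx[keep]] <- x[idx[keep]] + stats::dnorm(tt, mean = ev, sd = sigma)
    }
  }
  if (mean_subtract) x <- x - mean(x)
  structure(list(samples = x, times = (seq_len(n) - 1L) / fs, fs = fs,
                 kernel_sigma = sigma, mean_subtracted = mean_subtract),
            class = "convolved_train")
}

#' Sequential instantaneous rates
#'
#' Rates are calculated sequentially between events as the inverse of the
#' inter-event interval; each rate is timestamped at the later event of its
#' interval so it can be paired with simultaneous time-frequency measures.
#'
#' @param train An [event_train()].
#' @return Data frame with columns `time` (s) and `rate` (Hz); zero rows if
#'   the train has fewer than two events.
#' @export
sequential_rates <- function(train) {
  stopifnot(inherits(train, "event_train"))
  t <- train$times
  if (length(t) < 2L) {
    return(data.frame(time = numeric(0L), rate = numeric(0L)))
  }
  isi <- diff(t)
  data.frame(time = t[-1L], rate = 1 / isi)
}

#' Peri-stimulus time histogram
#'
#' Trial-averaged firing-rate estimate lambda(t): spike counts per bin divided
#' by (bin width x trial count), then Gaussian-smoothed with reflective edge
#' handling so the total count is conserved.
#'
#' @param trials A [trial_set()].
#' @param bin Bin width (s).
#' @param smooth_sigma Gaussian smoothing SD (s); 0 disables smoothing. The
#'   10 ms default keeps the 5 Hz stimulus envelope while removing gamma-band
#'   structure, which is what rate-matched surrogates require.
#' @return Data frame with `time` (bin centers, s) and `rate` (Hz), with the
#'   bin width stored in attribute `"bin"`.
#' @export
psth <- function(trials, bin = 0.001, smooth_sigma = 0.010) {
  stopifnot(inherits(trials, "trial_set"), bin > 0)
  n_bins <- max(1L, round(trials$duration / bin))
  edges <- (0:n_bins) * bin
  counts <- numeric(n_bins)
  for (tr in trials$trains) {
    if (length(tr$times)) {
      idx <- pmin(pmax(findInterval(tr$times, edges,
                                    rightmost.closed = TRUE), 1L), n_bins)
      tab <- tabulate(idx, nbins = n_bins)
      counts <- counts + tab
    }
  }
  rate <- counts / (bin * trials$n_trials)
  if (smooth_sigma > 0) {
    half <- ceiling(5 * smooth_sigma / bin)
    k <- stats::dnorm((-half:half) * bin, sd = smooth_sigma)
    k <- k / sum(k)
    # reflect the series at both edges so smoothing conserves total count
    padded <- c(rev(rate[seq_len(min(half, n_bins))]), rate,
                rev(rate)[seq_len(min(half, n_bins))])
    if (half > n_bins) {  # very short records: recycle reflection
      padded <- c(rep(rate, length.out = half), rate,
                  rep(rev(rate), length.out = half))
    }
    sm <- stats::filter(padded, k, sides = 2L)
    rate <- as.numeric(sm[(half + 1L):(half + n_bins)])
  }
  out <- data.frame(time = edges[-1L] - bin / 2, rate = rate)
  attr(out, "bin") <- bin
  out
}

#' CV2 series of a spike train
#'
#' Local measure of interspike-interval variability:
#' `CV2_i = 2 |I_{i+1} - I_i| / (I_{i+1} + I_i)` for consecutive ISI pairs
#' (Holt's pairwise formulation). CV2 is 0 for perfectly periodic firing,
#' about 1 for Poisson firing, and bounded by 2.
#'
#' @param train An [event_train()] with at least three events.
#' @return List of class `cv2_series`: `values`, `times` (time of the middle
#'   spike of each ISI pair), and `median` (NA with a flag if undefined).
#' @export
cv2_series <- function(train) {
  stopifnot(inherits(train, "event_train"))
  t <- train$times
  if (length(t) < 3L) {
    return(structure(list(values = numeric(0L), times = numeric(0L),
                          median = NA_real_, defined = FALSE),
                     class = "cv2_series"))
  }
  isi <- diff(t)
  i1 <- isi[-length(isi)]
  i2 <- isi[-1L]
  v <- 2 * abs(i2 - i1) / (i2 + i1)
  structure(list(values = v, times = t[2:(length(t) - 1L)],
                 median = stats::median(v), defined = TRUE),
            class = "cv2_series")
}

#' Relative firing-rate difference within a pair
#'
#' `|r_a - r_b| / ((r_a + r_b)/2)` with rates taken as trial-mean spike
#' counts over the window duration; ranges from 0 (equal rates) to 2 (one
#' silent cell). Large values attenuate phase-resetting-mediated
#' synchronization, which is why the population analyses track this quantity.
#'
#' @param pair A [pair_recording()].
#' @param window Length-2 numeric interval (s) over which rates are counted;
#'   defaults to the whole trial.
#' @return Scalar in `[0, 2]`, or `NA` (flagged via attribute `"defined"`)
#'   when neither cell fires in the window.
#' @export
relative_rate_difference <- function(pair, window = NULL) {
  stopifnot(inherits(pair, "pair_recording"))
  if (is.null(window)) window <- c(0, pair$duration)
  count_in <- function(ts) {
    mean(vapply(ts$trains, function(tr) {
      sum(tr$times >= window[1L] & tr$times <= window[2L])
    }, numeric(1L)))
  }
  w <- diff(window)
  ra <- count_in(pair$cell_a) / w
  rb <- count_in(pair$cell_b) / w
  if (ra + rb == 0) {
    return(structure(NA_real_, defined = FALSE))
  }
  structure(abs(ra - rb) / ((ra + rb) / 2), defined = TRUE)
}

#' Read an event-time table
#'
#' Delimited text with header columns `pair_id`, `cell_id`, `trial`,
#' `time_s`; returns one [pair_recording()] per pair id.
#'
#' @param path File path.
#' @param duration Trial duration in seconds (shared by all trials).
#' @param sep Field separator.
#' @param protocol Optional [protocol_config()] attached to every trial set.
#' @return Named list of `pair_recording` objects.
#' @export
read_event_table <- function(path, duration, sep = "\t", protocol = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("pair_id", "cell_id", "trial", "time_s")
  if (!all(need %in% names(df))) {
    stop("event table must have columns: ", paste(need, collapse = ", "))
  }
  out <- list()
  for (pid in unique(df$pair_id)) {
    sub <- df[df$pair_id == pid, ]
    cells <- sort(unique(sub$cell_id))
    if (length(cells) != 2L) {
      stop("pair ", pid, " must have exactly 2 cell ids, found ",
           length(cells))
    }
    trials <- sort(unique(sub$trial))
    mk <- function(cid) {
      trial_set(lapply(trials, function(tn) {
        event_train(sub$time_s[sub$cell_id == cid & sub$trial == tn],
                    duration = duration, label = cid)
      }), protocol = protocol)
    }
    out[[as.character(pid)]] <- pair_recording(mk(cells[1L]), mk(cells[2L]),
                                               pair_id = as.character(pid))
  }
  out
}

#' Write an event-time table
#'
#' @param pairs Named list of [pair_recording()] objects.
#' @param path Output file path.
#' @param sep Field separator.
#' @return Invisibly, the data frame written.
#' @export
write_event_table <- function(pairs, path, sep = "\t") {
  rows <- list()
  for (pid in names(pairs)) {
    p <- pairs[[pid]]
    for (side in c("cell_a", "cell_b")) {
      ts <- p[[side]]
      for (tn in seq_len(ts$n_trials)) {
        tr <- ts$trains[[tn]]
        if (length(tr$times)) {
          rows[[length(rows) + 1L]] <- data.frame(
            pair_id = pid, cell_id = side, trial = tn, time_s = tr$times)
        }
      }
    }
  }
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(df)
}
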