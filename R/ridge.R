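#' Dataset-wide ridge-detection threshold
#'
#' The pooled 95th percentile of band-limited (default 40-200 Hz) power
#' values across all time bins of all trial-averaged spectrograms in a
#' dataset. By construction about 5% of pooled band values exceed it, so
#' supra-threshold epochs reflect robust periodic synchrony (CPSD, symbol
#' "xi"), periodic firing (APSD, "lambda"), or periodic synaptic input
#' (IPSC-time CPSD, "zeta").
#'
#' @param spectrograms A `spectrogram` or list of them (one per pair/cell).
#' @param band Length-2 frequency band (Hz), inclusive.
#' @param percentile Percentile in (0, 100).
#' @param scope Optional dataset identifier recorded on the result.
#' @return Object of class `ridge_threshold` with fields `value`, `band`,
#'   `percentile`, `scope`, `n_values`.
#' @export
ridge_threshold <- function(spectrograms, band = c(40, 200),
                            percentile = 95, scope = NA_character_) {
  if (inherits(spectrograms, "spectrogram")) {
    spectrograms <- list(spectrograms)
  }
  stopifnot(length(spectrograms) >= 1L)
  pool <- unlist(lapply(spectrograms, function(sg) {
    sel <- sg$freqs >= band[1L] & sg$freqs <= band[2L]
    as.numeric(sg$power[sel, , drop = FALSE])
  }))
  if (!length(pool)) stop("no band-limited power values to pool")
  structure(list(value = as.numeric(stats::quantile(pool, percentile / 100)),
                 band = band, percentile = percentile, scope = scope,
                 n_values = length(pool)),
            class = "ridge_threshold")
}

#' @export
print.ridge_threshold <- function(x, ...) {
  cat(sprintf("<ridge_threshold> %gth percentile of %g-%g Hz power = %.4g (n=%d)\n",
              x$percentile, x$band[1L], x$band[2L], x$value, x$n_values))
  invisible(x)
}

# Supra-threshold local maxima along frequency for one time column.
# Plateaus resolve to their lowest-frequency bin.
.local_maxima <- function(p, thr) {
  n <- length(p)
  if (n == 1L) return(if (p >= thr) 1L else integer(0L))
  up <- c(TRUE, p[-1L] > p[-n])        # strictly rising into the bin
  down <- c(p[-n] >= p[-1L], TRUE)     # not rising out of it
  which(up & down & p >= thr)
}

#' Detect maximal ridges in a spectrogram
#'
#' Greedy time-frequency tracking of continuous high-power epochs. Per time
#' bin, band-limited supra-threshold local maxima along frequency are
#' located; tracking seeds at the global maximum and extends bidirectionally
#' to the nearest unclaimed supra-threshold local maximum in each adjacent
#' time bin, subject to the per-step continuity limit `|df|/dt <
#' continuity` (150 Hz/ms by default); claimed bins are removed and the
#' procedure repeats until no supra-threshold seeds remain. Equidistant
#' candidates tie-break toward the lower frequency. Ridges spanning fewer
#' than `min_bins` time bins are discarded.
#'
#' @param sg A `spectrogram`.
#' @param thr A [ridge_threshold()] or bare numeric threshold.
#' @param continuity Per-step frequency-slew limit (Hz/ms).
#' @param band Length-2 search band (Hz); defaults to the threshold's band.
#' @param min_bins Minimum ridge length in time bins.
#' @return Object of class `ridge_set`: a list of ridges, each with `times`,
#'   `freqs`, `powers`, `duration` (s), `mean_freq`, `mean_power`, and
#'   `slope` (Hz/ms, least-squares; negative = deceleration).
#' @export
detect_ridges <- function(sg, thr, continuity = 150, band = NULL,
                          min_bins = 2L) {
  stopifnot(inherits(sg, "spectrogram"))
  if (inherits(thr, "ridge_threshold")) {
    if (is.null(band)) band <- thr$band
    thr_val <- thr$value
  } else {
    thr_val <- as.numeric(thr)
    if (is.null(band)) band <- c(40, 200)
  }
  fsel <- which(sg$freqs >= band[1L] & sg$freqs <= band[2L])
  if (!length(fsel)) stop("spectrogram does not cover the band")
  P <- sg$power[fsel, , drop = FALSE]
  fr <- sg$freqs[fsel]
  nt <- ncol(P)
  dt_ms <- sg$hop * 1000
  max_df <- continuity * dt_ms
  # available local maxima per column (indices into fr)
  avail <- lapply(seq_len(nt), function(k) .local_maxima(P[, k], thr_val))
  ridges <- list()
  repeat {
    best <- -Inf
    seed <- NULL
    for (k in seq_len(nt)) {
      if (length(avail[[k]])) {
        j <- avail[[k]][which.max(P[avail[[k]], k])]
        if (P[j, k] > best) {
          best <- P[j, k]
          seed <- c(j, k)
        }
      }
    }
    if (is.null(seed)) break
    fidx <- integer(nt)  # 0 = not part of this ridge
    fidx[seed[2L]] <- seed[1L]
    step <- function(k_from, k_to, fidx_vec) {
      cand <- avail[[k_to]]
      if (!length(cand)) return(0L)
      df <- abs(fr[cand] - fr[fidx_vec[k_from]])
      ok <- df < max_df
      if (!any(ok)) return(0L)
      cand <- cand[ok]
      df <- df[ok]
      # nearest in frequency; ties toward the lower frequency
      cand[order(df, fr[cand])][1L]
    }
    k <- seed[2L]
    while (k < nt) {
      nxt <- step(k, k + 1L, fidx)
      if (nxt == 0L) break
      fidx[k + 1L] <- nxt
      k <- k + 1L
    }
    k <- seed[2L]
    while (k > 1L) {
      nxt <- step(k, k - 1L, fidx)
      if (nxt == 0L) break
      fidx[k - 1L] <- nxt
      k <- k - 1L
    }
    cols <- which(fidx > 0L)
    for (k in cols) avail[[k]] <- setdiff(avail[[k]], fidx[k])
    if (length(cols) >= min_bins) {
      tt <- sg$times[cols]
      ff <- fr[fidx[cols]]
      pp <- P[cbind(fidx[cols], cols)]
      slope <- if (length(cols) >= 2L) {
        unname(stats::coef(stats::lm(ff ~ tt))[2L]) / 1000
      } else NA_real_
      ridges[[length(ridges) + 1L]] <- list(
        times = tt, freqs = ff, powers = pp,
        duration = max(tt) - min(tt) + sg$hop,
        mean_freq = mean(ff), mean_power = mean(pp), slope = slope)
    }
  }
  if (length(ridges) > 1L) {
    ridges <- ridges[order(vapply(ridges, function(r) r$times[1L],
                                  numeric(1L)))]
  }
  structure(list(ridges = ridges, threshold = thr_val, band = band,
                 hop = sg$hop, kind = sg$kind),
            class = "ridge_set")
}

#' @export
print.ridge_set <- function(x, ...) {
  cat(sprintf("<ridge_set> %d %s ridge(s) above %.4g in %g-%g Hz\n",
              length(x$ridges), x$kind, x$threshold, x$band[1L], x$band[2L]))
  for (r in x$ridges) {
    cat(sprintf("  %.3f-%.3f s, mean %.1f Hz, slope %s Hz/ms\n",
                min(r$times), max(r$times), r$mean_freq,
                if (is.na(r$slope)) "NA" else sprintf("%.3f", r$slope)))
  }
  invisible(x)
}

#' Summarize ridges across a dataset
#'
#' Pools per-bin ridge frequencies and powers into empirical CDFs, collects
#' per-ridge least-squares slopes (Hz/ms), reports the fraction of pairs with
#' at least one ridge, and the per-50-ms-cycle-window occupancy: the fraction
#' of pairs with at least one ridge bin inside each consecutive window of the
#' average stimulation cycle.
#'
#' @param ridge_sets List of `ridge_set` objects, one per pair (or cell).
#' @param protocol A [protocol_config()]; needed for occupancy.
#' @param occupancy_window Cycle sub-window length (s).
#' @return List of class `ridge_summary`: `freqs`, `powers`, `slopes`,
#'   `freq_cdf`, `power_cdf` (functions), `fraction_with_ridge`, `occupancy`
#'   (per-window fractions), `n_pairs`.
#' @export
ridge_summary <- function(ridge_sets, protocol = NULL,
                          occupancy_window = 0.050) {
  stopifnot(is.list(ridge_sets))
  freqs <- unlist(lapply(ridge_sets, function(rs) {
    unlist(lapply(rs$ridges, `[[`, "freqs"))
  }))
  powers <- unlist(lapply(ridge_sets, function(rs) {
    unlist(lapply(rs$ridges, `[[`, "powers"))
  }))
  slopes <- unlist(lapply(ridge_sets, function(rs) {
    vapply(rs$ridges, `[[`, numeric(1L), "slope")
  }))
  has_ridge <- vapply(ridge_sets, function(rs) length(rs$ridges) > 0L,
                      logical(1L))
  occupancy <- NULL
  if (!is.null(protocol)) {
    period <- protocol$cycle_period
    nwin <- max(1L, round(period / occupancy_window))
    occ <- matrix(FALSE, nrow = length(ridge_sets), ncol = nwin)
    for (i in seq_along(ridge_sets)) {
      tt <- unlist(lapply(ridge_sets[[i]]$ridges, `[[`, "times"))
      if (length(tt)) {
        phase <- tt %% period
        wi <- pmin(floor(phase / occupancy_window) + 1L, nwin)
        occ[i, unique(wi)] <- TRUE
      }
    }
    occupancy <- colMeans(occ)
    names(occupancy) <- sprintf("%g-%g ms",
                                (seq_len(nwin) - 1L) * occupancy_window * 1000,
                                seq_len(nwin) * occupancy_window * 1000)
  }
  structure(list(freqs = freqs, powers = powers,
                 slopes = slopes[!is.na(slopes)],
                 freq_cdf = if (length(freqs)) stats::ecdf(freqs) else NULL,
                 power_cdf = if (length(powers)) stats::ecdf(powers) else NULL,
                 fraction_with_ridge = mean(has_ridge),
                 occupancy = occupancy, n_pairs = length(ridge_sets)),
            class = "ridge_summary")
}

#' Instantaneous firing rate versus simultaneous ridge frequency
#'
#' For each interspike interval whose later spike falls inside a ridge's
#' time span, pairs the instantaneous rate 1/ISI with the ridge frequency at
#' the nearest time bin. A mean ratio near 1 indicates firing on nearly
#' every oscillation cycle (dense synchrony); participation on every other
#' cycle halves it.
#'
#' @param pair A [pair_recording()] (spike times; absolute trial time base).
#' @param rset A `ridge_set` from the pair's CPSD spectrogram.
#' @param t_ref Offset (s) between the pair's absolute time base and the
#'   spectrogram/ridge time base (default: the protocol's first pulse onset,
#'   matching [cpsd_spectrogram()]).
#' @return List of class `rate_vs_ridge`: `samples` (data frame with `cell`,
#'   `time`, `rate`, `ridge_freq`, `ratio`), `mean_ratio` (named per cell),
#'   `overall_ratio`.
#' @export
rate_vs_ridge <- function(pair, rset, t_ref = NULL) {
  stopifnot(inherits(pair, "pair_recording"), inherits(rset, "ridge_set"))
  if (!length(rset$ridges)) stop("ridge set is empty")
  if (is.null(t_ref)) {
    pr <- pair$cell_a$protocol
    t_ref <- if (!is.null(pr)) pr$stim_onsets[1L] else 0
  }
  half <- rset$hop / 2
  lookup <- function(t) {  # ridge frequency at time t (ridge base), else NA
    for (r in rset$ridges) {
      if (t >= min(r$times) - half && t <= max(r$times) + half) {
        return(r$freqs[which.min(abs(r$times - t))])
      }
    }
    NA_real_
  }
  rows <- list()
  for (side in c("cell_a", "cell_b")) {
    for (tr in pair[[side]]$trains) {
      sr <- sequential_rates(tr)
      if (!nrow(sr)) next
      rf <- vapply(sr$time - t_ref, lookup, numeric(1L))
      ok <- !is.na(rf)
      if (any(ok)) {
        rows[[length(rows) + 1L]] <- data.frame(
          cell = side, time = sr$time[ok], rate = sr$rate[ok],
          ridge_freq = rf[ok], ratio = sr$rate[ok] / rf[ok])
      }
    }
  }
  if (!length(rows)) {
    return(structure(list(samples = data.frame(), mean_ratio = numeric(0L),
                          overall_ratio = NA_real_),
                     class = "rate_vs_ridge"))
  }
  samples <- do.call(rbind, rows)
  mean_ratio <- tapply(samples$ratio, samples$cell, mean)
  structure(list(samples = samples,
                 mean_ratio = mean_ratio,
                 overall_ratio = mean(mean_ratio)),
            class = "rate_vs_ridge")
}

#' Export ridges as a delimited table
#'
#' @param rset A `ridge_set`.
#' @param path Output path.
#' @param pair_id Identifier written in the first column.
#' @param sep Field separator.
#' @export
write_ridges <- function(rset, path, pair_id = NA_character_, sep = "\t") {
  rows <- lapply(seq_along(rset$ridges), function(i) {
    r <- rset$ridges[[i]]
    data.frame(pair_id = pair_id, ridge_id = i, time_s = r$times,
               freq_hz = r$freqs, power = r$powers)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pair_id = character(0L), ridge_id = integer(0L),
               time_s = numeric(0L), freq_hz = numeric(0L),
               power = numeric(0L))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(df)
}
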