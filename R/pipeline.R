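# Tiny FNV-1a hash of a serialized R object; stamps outputs so reruns can be
# matched to the configuration that produced them.
.config_hash <- function(x) {
  raw <- as.integer(serialize(x, NULL, version = 2L))
  h <- 5381
  for (b in raw) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Analysis configuration
#'
#' Gathers every named constant of the pipeline, with defaults equal to the
#' stated analysis conventions: 10 kHz sampling, 1 ms convolution kernel,
#' 100 ms / 95%-overlap Hamming Welch windows (500 ms for the theta band),
#' 95th-percentile ridge thresholds over 40-200 Hz with a 150 Hz/ms
#' continuity limit, +/-5 ms spike and +/-1 ms IPSC synchrony windows,
#' 2.5x-noise-SD IPSC amplitude rule, and the STO rules (10-150 Hz, <= 30
#' Hz/ms, 20% frequency deviation, >= 2 periods, r2 gate 0.40, >= 10 events
#' for resonance).
#'
#' @param ... Named overrides of any default.
#' @return List of class `analysis_config`, with a `hash` field recorded in
#'   all downstream outputs.
#' @export
analysis_config <- function(...) {
  cfg <- list(
    fs = 10000, kernel_sigma = 0.001,
    welch = list(window = 0.100, overlap = 0.95, taper = "hamming"),
    theta = list(band = c(2, 12), window = 0.500),
    ridge = list(band = c(40, 200), percentile = 95, continuity = 150,
                 min_bins = 2L),
    sync_windows = list(spike = 0.005, ipsc = 0.001,
                        w_grid = c(0.5, 1, 2, 3, 4, 5) / 1000),
    surrogate = list(n_repeats = 10L, psth_bin = 0.001,
                     psth_sigma = 0.010),
    ipsc = list(criterion_threshold = 3, amplitude_sd_mult = 2.5),
    sto = list(band = c(10, 150), continuity = 30, max_freq_dev = 0.20,
               min_periods = 2, r2_gate = 0.40, resonance_threshold = 10L,
               steps_pa = seq(50, 500, by = 50)),
    max_lag = 0.25)
  over <- list(...)
  for (nm in names(over)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      utils::modifyList(cfg[[nm]], over[[nm]])
    } else {
      over[[nm]]
    }
  }
  cfg$hash <- .config_hash(cfg[setdiff(names(cfg), "hash")])
  class(cfg) <- "analysis_config"
  cfg
}

#' Run the spike-synchrony analysis over a dataset of pairs
#'
#' The full per-pair and dataset-level pipeline: surrogate-corrected
#' cross-correlogram peaks, CPSD spectrograms, per-cell APSD spectrograms
#' and CV2, dataset-level ridge thresholds (computed before any per-pair
#' ridge detection, as the thresholds pool the whole dataset), ridge
#' detection and summaries, rate-vs-ridge-frequency coupling, and
#' theta-band CPSD averages.
#'
#' @param pairs Named list of [pair_recording()] objects.
#' @param config An [analysis_config()].
#' @param seed Integer seed controlling surrogate generation.
#' @return List of class `synchrony_report`; see elements `pairs`
#'   (per-pair results), `xi`, `lambda` (thresholds), `cpsd_summary`,
#'   `apsd_summary`, `config_hash`, `seed`.
#' @export
run_spike_analysis <- function(pairs, config = analysis_config(),
                               seed = 1L) {
  stopifnot(length(pairs) >= 1L,
            all(vapply(pairs, inherits, logical(1L), "pair_recording")))
  if (is.null(names(pairs))) names(pairs) <- paste0("pair", seq_along(pairs))
  set.seed(seed)
  fs <- config$fs
  sig <- config$kernel_sigma
  w <- config$welch
  per <- list()
  for (pid in names(pairs)) {
    p <- pairs[[pid]]
    cg <- cross_correlogram(p, max_lag = config$max_lag,
                            mean_subtract = TRUE, fs = fs, sigma = sig)
    null <- null_correlogram(p, n_repeats = config$surrogate$n_repeats,
                             max_lag = config$max_lag, mean_subtract = TRUE,
                             fs = fs, sigma = sig)
    peak <- correlogram_peak(cg, null,
                             half_window = config$sync_windows$spike)
    sg <- cpsd_spectrogram(p, window = w$window, overlap = w$overlap,
                           fs = fs, sigma = sig)
    theta_sg <- cpsd_spectrogram(p, window = config$theta$window,
                                 overlap = w$overlap, fs = fs, sigma = sig)
    theta_power <- band_average(theta_sg, config$theta$band[1L],
                                config$theta$band[2L])
    apsd <- list(
      cell_a = apsd_spectrogram(p$cell_a, window = w$window,
                                overlap = w$overlap, fs = fs, sigma = sig),
      cell_b = apsd_spectrogram(p$cell_b, window = w$window,
                                overlap = w$overlap, fs = fs, sigma = sig))
    cv2 <- lapply(c(a = "cell_a", b = "cell_b"), function(side) {
      med <- vapply(p[[side]]$trains, function(tr) cv2_series(tr)$median,
                    numeric(1L))
      stats::median(med, na.rm = TRUE)
    })
    per[[pid]] <- list(pair = p, correlogram = cg, null = null,
                       corrected_peak = peak, cpsd = sg,
                       theta_power = theta_power, apsd = apsd, cv2 = cv2)
  }
  # dataset thresholds pool every spectrogram before per-pair detection
  xi <- ridge_threshold(lapply(per, `[[`, "cpsd"),
                        band = config$ridge$band,
                        percentile = config$ridge$percentile,
                        scope = "spike CPSD")
  lambda <- ridge_threshold(unlist(lapply(per, function(x) x$apsd),
                                   recursive = FALSE),
                            band = config$ridge$band,
                            percentile = config$ridge$percentile,
                            scope = "spike APSD")
  for (pid in names(per)) {
    per[[pid]]$cpsd_ridges <- detect_ridges(
      per[[pid]]$cpsd, xi, continuity = config$ridge$continuity,
      min_bins = config$ridge$min_bins)
    per[[pid]]$apsd_ridges <- lapply(per[[pid]]$apsd, detect_ridges,
                                     thr = lambda,
                                     continuity = config$ridge$continuity,
                                     min_bins = config$ridge$min_bins)
    per[[pid]]$rate_vs_ridge <-
      if (length(per[[pid]]$cpsd_ridges$ridges)) {
        rate_vs_ridge(per[[pid]]$pair, per[[pid]]$cpsd_ridges)
      } else {
        NULL
      }
  }
  proto <- pairs[[1L]]$cell_a$protocol
  structure(list(
    pairs = per, xi = xi, lambda = lambda,
    cpsd_summary = ridge_summary(lapply(per, `[[`, "cpsd_ridges"),
                                 protocol = proto),
    apsd_summary = ridge_summary(unlist(lapply(per, `[[`, "apsd_ridges"),
                                        recursive = FALSE),
                                 protocol = proto),
    config_hash = config$hash, seed = seed),
    class = "synchrony_report")
}

#' @export
print.synchrony_report <- function(x, ...) {
  cat(sprintf(
    "<synchrony_report> %d pairs | CPSD ridge prevalence %.0f%% | APSD %.0f%% | config %s seed %d\n",
    length(x$pairs), 100 * x$cpsd_summary$fraction_with_ridge,
    100 * x$apsd_summary$fraction_with_ridge, x$config_hash, x$seed))
  invisible(x)
}

# TC vs MC grouping of a pair: "TC" if both cells are tufted subtypes,
# "MC" if both mitral, otherwise "mixed".
.pair_group <- function(pair) {
  tc <- c("sTC", "mTC", "dTC")
  if (all(pair$cell_types %in% tc)) return("TC")
  if (all(pair$cell_types == "MC")) return("MC")
  "mixed"
}

#' Group-level report over one or more analysis bundles
#'
#' Pools per-pair results by cell-type group, tabulates ridge prevalence
#' with a 2x2 chi-squared comparison (when two groups are present),
#' frequency/power distributions, cycle-window occupancy, corrected
#' correlogram peaks, CV2 medians, and theta-band power.
#'
#' @param reports A `synchrony_report` or list of them.
#' @return List of class `synchrony_group_report`.
#' @export
run_reports <- function(reports) {
  if (inherits(reports, "synchrony_report")) reports <- list(reports)
  per <- unlist(lapply(reports, `[[`, "pairs"), recursive = FALSE)
  groups <- vapply(per, function(x) .pair_group(x$pair), character(1L))
  has_ridge <- vapply(per, function(x) length(x$cpsd_ridges$ridges) > 0L,
                      logical(1L))
  prevalence <- tapply(has_ridge, groups, mean)
  counts <- table(groups, factor(has_ridge, levels = c(TRUE, FALSE)))
  chi2 <- NULL
  if (nrow(counts) == 2L && all(rowSums(counts) > 0) &&
      all(colSums(counts) > 0)) {
    chi2 <- chi2_2x2(matrix(as.numeric(counts), nrow = 2L))
  }
  peaks <- vapply(per, `[[`, numeric(1L), "corrected_peak")
  theta <- vapply(per, `[[`, numeric(1L), "theta_power")
  cv2 <- vapply(per, function(x) {
    mean(unlist(x$cv2), na.rm = TRUE)
  }, numeric(1L))
  structure(list(
    n_pairs = length(per), groups = groups,
    prevalence = prevalence, prevalence_counts = counts,
    prevalence_chi2 = chi2,
    corrected_peaks = peaks, theta_power = theta, cv2_medians = cv2,
    cpsd_summary = ridge_summary(lapply(per, `[[`, "cpsd_ridges"),
                                 protocol = per[[1L]]$pair$cell_a$protocol),
    config_hash = reports[[1L]]$config_hash),
    class = "synchrony_group_report")
}

#' @export
print.synchrony_group_report <- function(x, ...) {
  cat(sprintf("<synchrony_group_report> %d pairs\n", x$n_pairs))
  for (g in names(x$prevalence)) {
    cat(sprintf("  %s: %.0f%% with >=1 CPSD ridge\n", g,
                100 * x$prevalence[[g]]))
  }
  if (!is.null(x$prevalence_chi2)) {
    cat("  prevalence ")
    print(x$prevalence_chi2)
  }
  invisible(x)
}
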