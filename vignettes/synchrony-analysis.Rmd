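---
title: "Methods: spike-time synchrony, oscillation ridges, and resonance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spike-time synchrony, oscillation ridges, and resonance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synchridge)
```

This vignette is the package's account of its methods: the models behind
each stage, the tunable parameters and why their defaults are what they
are, what the synthetic-data generators do and do not emulate, and the
numerical choices made where the procedure left room.

## The analysis model

The package analyzes paired recordings of neurons driven by a repeating
theta-paced stimulus (by default five 10 ms pulses at a 200 ms
inter-pulse interval). Its central object is the *convolved event train*:
each spike or synaptic-event time is replaced by a unit-area Gaussian
(σ = 1 ms by default, matching the uncertainty of threshold-based event
detection across cells), sampled at 10 kHz, and mean-subtracted. Unit
area preserves the rate interpretation — without mean subtraction the
signal integrates to the event count, and the cross-correlogram baseline
of two independent trains is the product of their mean rates, a useful
analytic check.

**Cross-correlograms.** Per trial,
`C(τ) = (1/T) ∫ s_a(t) s_b(t+τ) dt`, averaged across trials (averaging
after per-trial correlation, not on concatenated records, so cross-trial
phase is irrelevant). Positive τ means events of the second cell lag the
first. Because slow (stimulus-locked) rate co-modulation also produces a
central correlogram peak, fast-timescale synchrony is always assessed
against a *rate-matched surrogate null*: independent inhomogeneous
Poisson processes whose rate function λ(t) is the trial-averaged PSTH.
The corrected central peak is the maximum of (experimental − null) over
|τ| ≤ 5 ms, the synchronous-spike window.

**Spectrograms.** Welch cross-spectra of the convolved trains with a
100 ms Hamming window and 95% overlap: one tapered segment per time bin,
giving 10 Hz frequency resolution on a 5 ms time grid. Power is the
trial-averaged cross-spectral magnitude `|S12(f)|` with the standard
Welch scaling, so the auto-spectrogram (APSD) equals the textbook PSD
estimate. The alternative, magnitude-squared, changes every value
monotonically and none of the thresholded or comparative results; we use
magnitude so that APSD retains its usual units. Magnitude is taken
*within* trials before averaging, preserving within-trial synchrony
regardless of cross-trial phase. Theta-band (2–12 Hz) analyses cannot be
resolved by a 100 ms window; they use a 500 ms window (2 Hz resolution)
at the same overlap fraction.

**Ridges.** Epochs of robust periodic synchrony (CPSD), periodic firing
(APSD), or periodic synaptic input (IPSC-time CPSD) are continuous
supra-threshold tracks in the spectrogram. The threshold is the pooled
95th percentile of 40–200 Hz power across all time bins of all
trial-averaged spectrograms of a dataset — by construction ~5% of pooled
band values exceed it, so it is computed dataset-wide *before* any
per-pair detection. Tracking is greedy: per time bin, band-limited
supra-threshold local maxima along frequency are found; the global
maximum seeds a ridge extended bidirectionally to the nearest unclaimed
supra-threshold local maximum per adjacent time bin, subject to the
per-step continuity limit |Δf|/Δt < 150 Hz/ms; claimed bins are removed
and the search repeats. Ties between equidistant candidates resolve
toward the lower frequency (consistent with the decelerating-chirp
phenomenology of gamma in this system); seeding at the global maximum
makes extraction deterministic. At the default 5 ms hop, 150 Hz/ms
permits 750 Hz per-step jumps, so segmentation is primarily
threshold-driven; the limit is enforced per consecutive-bin step. Ridges
shorter than 2 time bins (10 ms) are discarded — no minimum duration
beyond "continuous" is imposed, and 2 bins is the smallest span that is
continuous at all.

**Rate–frequency coupling.** For each interspike interval whose later
spike falls inside a ridge's span, the instantaneous rate 1/ISI is paired
with the ridge frequency at the nearest time bin (rates are timestamped
at the later event of each interval throughout the package, which is
what lets them be matched to time–frequency bins). A mean
rate : frequency ratio near 1 indicates firing on nearly every
oscillation cycle — dense synchrony; participation on alternate cycles
halves it.

## IPSC detection and synchrony decomposition

Events are detected by sliding-template matching (Clements–Bekkers): at
each offset the unit-peak biexponential template
`g(t) = (1 − e^{−t/τ_rise}) e^{−t/τ_decay}` (0.4 / 3.0 ms, 4.0 ms total
with a 1.0 ms flat baseline) is fitted by least squares for scale and
offset; the detection criterion is scale / standard error of the fit.
Candidates are local criterion maxima exceeding the criterion threshold
(default 3.0 — the matching statistic needs its own cutoff, which the
amplitude rule alone does not provide) *and* the amplitude rule
(fitted scale ≥ 2.5× the SD of a designated event-free baseline
segment); events closer than 0.5 ms merge, keeping the larger criterion.
Event time is reported at the onset of the template's rising phase
(window start + baseline), a convention that is consistent across cells
— which is all the |Δt| classification requires — and aligns detected
times with the generator's ground truth. Amplitude is the fitted scale
relative to the fitted offset.

Per-event 20–80% rise times interpolate linearly between samples. Decay
constants of individual events are unreliable during barrages, so a
single constant per cell is fitted to the peak-aligned median waveform —
starting 1 ms after the peak, because immediately after the peak the
residual rise term slows the apparent decay and biases a
single-exponential fit upward by about 6% (verified analytically; the
1 ms delay reduces the bias below 1%).

Synchrony decomposition classifies each event independently: synchronous
iff any partner event in the other cell lies within ±w (default 1 ms).
Independent classification makes the decomposition exactly symmetric
under swapping the pair, and yields the closed form
`F_synch(w) = 1 − e^{−2rw}` for independent Poisson trains of rate r,
which the tests exploit as an analytic oracle.

## Subthreshold oscillations

Spikes are removed by linear interpolation from 1 ms before their
threshold crossing to the return within 1 mV of the pre-spike level
(capped at +10 ms; overlapping spans merge). The subthreshold trace is
transformed with an analytic Morlet wavelet (center-frequency parameter
6) on a 1 Hz grid from 10 to 150 Hz.

Candidate STOs are extracted iteratively. The global scalogram maximum
seeds a ridge extended per time step to the magnitude maximum within the
continuity limit (≤ 30 Hz/ms). The candidate epoch is the contiguous
stretch around the maximum over which the ridge stays above a *relaxed
magnitude threshold* and its frequency stays within 20% of the maximum
frequency; candidates shorter than 2 periods are rejected. A sinusoid
with amplitude fixed to the segment SD, offset to the segment mean, and
frequency to the ridge maximum is fitted for phase alone (closed form:
`φ = atan2(−Σṽ sin θ, Σṽ cos θ)`), and the candidate is confirmed when
the fit's r² reaches the gate (default 0.40) — an automated stand-in for
the post-hoc visual confirmation a human operator would perform, and
deliberately surfaced as a configuration parameter since any such gate is
a judgment call. Note one systematic of this recipe: for a pure sinusoid
of amplitude A the fitted amplitude is A/√2 (the SD of a sinusoid).

The relaxed threshold is the 90th percentile of band-limited scalogram
magnitude. It earns its name by sitting far below any real ridge maximum
(on a noise-dominated trace ~10% of all bins exceed it), but it is not
optional: a Morlet atom at center parameter 6 smears an oscillation about
one period beyond each epoch edge, and within that smear both the argmax
frequency and the phase-gradient instantaneous frequency of band-filtered
noise stay inside the 20% tolerance. Without a magnitude cut the
candidate span therefore absorbs ~1.5 periods of pure noise per edge,
which both inflates the duration and dilutes the fixed-amplitude r² to
the point of rejecting genuine oscillations. With the cut, recovered
durations land within one period of ground truth and noise-only traces
yield no confirmed events.

Confirmed epochs are claimed (at most one STO per temporal epoch;
overlaps resolve to the larger ridge maximum, which is extracted first).
A *rejected* candidate does not claim its epoch — it only suppresses its
own frequency neighborhood there, the automated analogue of iterating
with progressively refined frequency bounds — otherwise a low-frequency
transient (e.g., a step-current edge) would permanently block the epochs
it overlaps.

A cell is *resonant* iff it shows ≥ 10 confirmed STOs across the step
protocol (50–500 pA in 50 pA steps, one trial each — one event per step
on average). Post-STO spikes (within two periods after the STO end) get
phases extrapolated from the fit in cosine convention (0 = peak,
reported in (−π, π]; the reference is the last fitted peak inside the
STO), and their sequential rates — the inverse interval ending at each
qualifying spike — are paired with the STO frequency. The sequential
convention matters: a cell firing on alternate periods has exactly one
qualifying spike per STO, whose rate (measured against its predecessor)
is f/2, giving the expected 1:2 ratio.

When validating end-to-end phase recovery, phase is compared at the
center of the detected epoch: the fit anchors phase mid-segment, so a
1 Hz frequency-grid quantization rotates the *absolute* phase constant by
hundreds of degrees while the oscillation's phase near the segment —
what spike-phase extrapolation actually uses — stays accurate to a few
degrees.

## Synthetic data: what it emulates, and what it does not

The generators encode the study conditions every test runs under:

* `synchronous_pair()` — a per-cycle common oscillator whose frequency
  sweeps linearly (defaults: 150 ms active window per 200 ms cycle,
  10 ms onset delay, 10 trials, 1 ms Gaussian spike jitter, 80% per-peak
  Bernoulli participation), with both cells' spikes tied to the same
  oscillator peaks. Trials mimic the ~10-trial sessions of paired
  recordings.
* `poisson_surrogate()` — Lewis–Shedler thinning against the PSTH
  (1 ms bins, 10 ms Gaussian smoothing — wide enough to erase gamma-band
  structure, narrow enough to preserve the 5 Hz envelope), 10 surrogate
  datasets per null by default.
* `ipsc_trace()` — sums of unit-peak template waveforms plus white
  noise, outward-positive.
* `sto_trace()` — baseline, step depolarization, sinusoidal STO epochs,
  and stereotyped 2 ms triangular spikes to +30 mV (only their
  interpolability matters), plus white noise.

These fixtures are phenomenological. They do not model conductances,
phase-response curves, synaptic depression, electrode artifacts, or the
correlated (non-white) membrane noise of real recordings; passing tests
demonstrate that the *analysis* recovers what the generators put in, not
that real tissue behaves like the generators. In particular, surrogate
pairs rate-matched to dense gamma-participating cells genuinely carry
chance-level slow-gamma CPSD — that is the very phenomenon the
percentile threshold and the surrogate correction exist to handle, and
it is why dataset composition (strongly synchronized pairs raising the
pooled threshold above the chance level of weaker pairs) shapes ridge
prevalence.

## Numerical choices and degenerate inputs

* Kernels are truncated at ±5σ without edge renormalization; events
  within 5σ of a record edge lose mass, so analysis windows should be
  padded accordingly (the generators pad by 100 ms).
* PSTH smoothing reflects the series at both edges, conserving total
  count to machine precision.
* Correlograms and spectrogram segments are computed by FFT with
  power-of-two padding; correlogram units are signal-squared (rate²),
  and all comparative results are invariant to the overall
  normalization.
* Empty trains are valid everywhere they can be (zero signal, zero
  correlogram, empty ridge set); undefined statistics (CV2 with < 3
  events, decay with < 5 events, rate differences of two silent cells)
  return flagged `NA`s rather than numbers.
* Percentiles use R's default quantile definition (type 7).
* The Watson–Williams concentration correction uses Fisher's
  approximation for κ from the pooled mean resultant length, with a
  low-concentration flag below 0.45. Benjamini–Hochberg adjustment
  delegates to `stats::p.adjust(method = "BH")` — base R already
  implements the step-up exactly — and is verified in the tests against
  an independently coded oracle. The chi-squared statistic is Pearson's
  without continuity correction, the convention required to reproduce
  the printed prevalence comparisons.

## Interfaces

The package's functions are its interface: `run_spike_analysis()` and
`run_reports()` orchestrate the per-dataset pipeline over the same
building blocks documented above, with `analysis_config()` holding every
named constant (and a content hash recorded in outputs so results can be
matched to the configuration that produced them). Event tables, traces,
correlograms, spectrograms, and ridge sets read/write plain delimited
text.

## Problem sizes

The test-suite and acceptance runs use 1.2 s five-cycle protocols with
5–10 trials per pair, 10–20 s IPSC traces at 10 kHz, 1.5 s voltage
traces at 2 kHz, and 25–50 random seeds per recovery sweep — sizes at
which every stage's behavior is already asymptotic while a full run
completes in minutes on one CPU.

## Known limitations

* Ridge tracking follows single per-bin local maxima; two oscillations
  closer than one frequency-resolution bin merge.
* The 150 Hz/ms continuity limit is permissive at a 5 ms hop, so CPSD
  ridge segmentation is effectively threshold-driven.
* The r² confirmation gate is a proxy for expert visual confirmation;
  its default (0.40) is a configuration choice, and confirmed-STO counts
  are non-increasing in it.
* Coherence is deliberately not computed: the synchrony measure is
  magnitude CPSD, not a normalized coherence, so rate scale enters the
  measure (and is controlled for via the surrogate null).
* Sequential 1/ISI rates are biased above the mean rate for irregular
  trains (Jensen's inequality) — intended, as they measure instantaneous
  rather than average firing.
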