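Package: synchridge
Title: Spike-Time Synchrony and Network-Oscillation Analysis for Paired Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing fast network oscillations in paired
    electrophysiological recordings. Implements surrogate-corrected
    cross-correlograms of convolved event trains, Welch cross- and auto-power
    spectral density spectrograms with time-frequency ridge tracking,
    template-matching detection of inhibitory postsynaptic currents with
    synchronous/asynchronous decomposition, Morlet-wavelet detection of
    subthreshold membrane-potential oscillations with resonance
    classification and circular spike-phase statistics, and synthetic-data
    generators that emulate theta-paced, gamma-synchronized firing for
    validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
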