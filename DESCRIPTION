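Package: mmse
Title: Modified Multiscale Sample Entropy for Electrophysiological Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Multiscale sample entropy estimation for neurophysiological
    time series with explicit control over the two choices that couple
    entropy estimates to spectral power: the similarity bound (global
    versus scale-wise) and the scale-wise coarse-graining filter
    (point averaging, low-, high-, band-pass or band-stop, followed by
    point skipping with refined-composite counting across offsets and
    discontinuous segments). Includes generators for band-limited 1/f
    background noise with superimposed phase-locked rhythms, power
    spectral density and aperiodic slope estimation with rhythm-band
    exclusion, phase-randomisation surrogates, a simplified
    oscillation-episode detector based on wavelet power against a
    fitted 1/f background, and small effect-size helpers.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
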