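Package: ultrarhythm
Title: Ultradian Rhythms and Fractal Dynamics in High-Resolution Locomotor
    Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Joint analysis of periodic (circadian and ultradian) rhythms and
    fractal (scale-invariant) dynamics in long, high-resolution binary
    locomotion records, such as week-long home-cage ambulation series sampled
    every 0.5 seconds. Provides actogram construction and ambulation
    summaries; Fourier power spectra with peak significance and spectral
    slope; the Enright chi-square periodogram with peak sorting and harmonic
    removal; empirical mode decomposition by cubic-spline sifting with
    per-mode spectra and a principal-peak histogram; the complex Morlet
    continuous wavelet transform with peak lag-time quantification and
    cross-individual synchrony via Spearman correlation of the real
    coefficients; detrended fluctuation analysis with scaling-range selection
    and a circadian comb-filter control; immobility/mobility bout extraction
    with power-law versus exponential duration-distribution fits; and a
    synthetic generator producing binary series with controlled rhythm
    mixtures, long-range correlations and power-law immobility bouts, so that
    every stage of the pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
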