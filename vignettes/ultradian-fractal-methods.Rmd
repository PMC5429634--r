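---
title: "Rhythm and fractal analysis of high-resolution locomotor records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rhythm and fractal analysis of high-resolution locomotor records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ultrarhythm)
```

## The problem

Animal locomotion recorded at high temporal resolution over many days
carries two kinds of temporal organization at once: smooth periodic rhythms
— the circadian (~24 h) cycle and faster *ultradian* rhythms (12, 8, 6,
4.8, 4 h and below) — and *fractal* (scale-invariant) dynamics: long-range
correlated fluctuations and power-law distributed bouts of immobility.
`ultrarhythm` implements a joint analysis of both regimes for binary
activity records (one 0/1 sample per interval, canonically 0.5 s over
~6.5 days, i.e. ~1.07e6 samples per animal), together with a synthetic
generator that reproduces the statistical structure the analyses assume, so
that every stage is testable without any recorded data.

The package is organized as an analysis workflow: the numbered scripts in
`analysis/` are thin narrative drivers over the functions documented here,
writing their tables under `results/`.

## Data representation

A `locomotion_series` holds the 0/1 samples, the sampling interval, the
clock time of the first sample and a per-sample exclusion mask for
housekeeping gaps (cage maintenance).  Excluded samples are dropped and the
series analyzed as if concatenated; fluctuation exponents are insensitive
to random data loss far beyond the few-percent gaps this represents, and
the constructor refuses series with 65% or more excluded.  Actograms are
percent-time-ambulating per bin: 6-min bins for display, wavelet and
Enright analysis (to suppress sample-level noise), 30 s bins upstream of
empirical mode decomposition (a compromise between noise pooling and the
number of points available for per-mode spectra).  Clock bookkeeping uses
each bin's left edge, and actogram folding for the median day uses the
record's first bin as the day origin; any fixed convention works, but it
must be shared by all animals for synchrony comparisons to be meaningful.

Partial trailing bins are dropped rather than padded (padding would bias
the percent estimate of the last bin); a fully excluded bin is missing
(`NA`), never zero.

## Periodograms

`power_spectrum()` computes the one-sided periodogram, normalized so the
ordinates sum to the series variance (Parseval), with periods in hours.
`peak_significance()` tests ordinates against the white-noise null, under
which normalized ordinates are approximately unit-exponential.  The default
flags each frequency at the requested level (so a level of 0.001 flags
about 0.1% of frequencies on pure noise, which is how the calibration
tests read it); a Šidák family-wise correction is available where a
single spectrum is screened for "any" peak.  `spectral_slope()` fits
`log S(f)` against `log f`; the negated slope is the spectral exponent
`beta`, related to the fluctuation exponent by `beta = 2 * alpha - 1`,
and this identity is used throughout the tests as a cross-check between
the spectral and fluctuation routes.

`enright_periodogram()` implements the chi-square periodogram in the
Sokolove–Bushell normalization: the series is folded at each trial period
`P` (in bins, from 2 to N/2; a one-bin period is degenerate), and
`Q_P = N * var(phase means) / var(series)` is referred to chi-square with
`P - 1` degrees of freedom.  Two properties matter in practice.  First,
`Q_P` is scale- and offset-free.  Second, the chi-square reference is
conservative where the record folds into only a few blocks (trial periods
approaching N/2): the between-phase sum of squares is then a large share of
the total and the statistic is bounded well below the chi-square tail.  The
acceptance tests therefore calibrate the type-I error on the full trial
range (never anticonservative) and tightly on the well-resolved subrange
(at least 10 folded blocks).

`enright_select_peaks()` applies the associated peak-reading rule: local
maxima above 10% of the global maximum, sorted by ascending period, then
every period that is an integer multiple (within half a bin) of a retained
shorter period is removed, because the folding statistic cannot tell a
rhythm from its harmonics.  When a period and its multiple both qualify,
the shorter is kept — the ascending processing order implies it; this is an
interpretation, made explicit here.  Periods that are such multiples are
*removed* rather than merely left untested; the significance flags of the
surviving periods are reported unchanged.

## Empirical mode decomposition

`emd_decompose()` is classic sifting: natural cubic-spline envelopes
through the local maxima and minima, with the two outermost extrema
mirrored beyond each end (without mirroring, envelope end-swings corrupt
the slow modes of a multi-day record), iterating on the envelope-mean
residual.  The default stopping rule is the Rilling criterion — sift until
the relative envelope mean `|m|/a` is below 0.05 on all but 5% of the
record and below 0.5 everywhere — which is the default of the classic
open-source EMD toolbox this implementation follows; the Huang SD
criterion (threshold 0.2) is available as `stop_rule = "sd"`.  A mode is
accepted only when its extrema and zero-crossing counts differ by at most
one (the IMF definition), and decomposition continues while the residual
retains at least three extrema.  No detrending or denoising is applied
before decomposition.  The decomposition is complete by construction:
IMFs plus residual reproduce the input to machine precision, and the test
suite asserts reconstruction below 1e-8 relative error.

On records of this geometry (about 18,700 thirty-second bins) canonical
EMD behaves as a dyadic filter bank and yields close to `log2(N) ~ 14`
modes; the realized count is 12–14 depending on the realization.  Real
records, with their idiosyncratic slow nonstationarity, can sit at the
upper edge of that range or above it; the synthetic generator emulates this
with a smooth random across-day drift (see below), but a count of at least
14 for every synthetic animal is not guaranteed, and the corresponding
end-to-end check documents this as a known limitation.

`principal_peaks()` applies the rhythm-attribution rule: within a
contiguous window of 4 IMFs (by default auto-selected to cover the
circadian-to-4 h band; the window is a parameter), collect each mode's
spectral peaks exceeding 30% of that spectrum's maximum and keep the 10
largest.  Contiguity of the window is an interpretation the implementation
makes explicit.  `peak_histogram()` pools the retained peak periods across
animals.

## Wavelet analysis and synchrony

`cwt_morlet()` convolves the mean-subtracted actogram with scaled complex
Morlet atoms (`cmor1-1.5`: bandwidth 1, center frequency 1.5), scales 1–400
by default.  The scale-to-period map is
`period = scale * bin_seconds / (3600 * fc)` hours, so 6-min bins cover
0.067–26.7 h.  Mean subtraction removes the DC offset that otherwise
dominates the large scales.  The transform is linear and the coefficients
are exposed as a complex matrix (modulus, phase and real views derive from
it).

`peak_lag_times()` detects prominent local maxima of the real coefficients
at the row nearest a requested period: prominence at least 10% of the row's
range, separation at least half the period (both parameters).  If a rhythm
of that period is truly present, successive peak-to-peak lags average to
the period itself — the lag plot is the analytical confirmation.  Peaks are
counted over the full row, including within one period of the edges: the
signature count of 13 peaks at the 12 h scale over a 6.5-day record (2 per
day) includes the first and last peaks, which the attenuated edge response
does not suppress given the prominence rule.

`synchrony()` computes, per scale, the Spearman rank correlation over time
between the real coefficients of two animals, excluding one period at each
edge (the cone of influence, where convolution sees the zero-padded
boundary).  Rank correlation makes the profile invariant to any monotone
per-scale normalization, so correlating raw rather than intensity-scaled
coefficients is immaterial.  `group_synchrony()` averages over all pairs.
A caveat the tests respect: at scales whose period is a large fraction of
the record, the effective number of independent coefficient samples is
small (roughly the number of cycles), so pairwise `rho` between genuinely
independent records is noisy there; the no-synchrony calibration is
asserted where the estimator is well resolved (periods up to ~6 h on a
6.5-day record), while shared rhythms still stand out clearly at their own
scales against the pair-averaged profile.

## Detrended fluctuation analysis

`dfa()` is the standard procedure: integrate the mean-subtracted series,
partition into non-overlapping windows (from both ends, so all data are
used), detrend each window with a polynomial, and take the RMS residual
`F(n)`; `alpha` is the slope of `log F` vs `log n`.  Order 3 is the
default: on multi-day activity records it is the lowest order that removes
slow rhythm-scale trends (the tests show order 1 fails and order >= 3
succeeds on cubic-contaminated noise, while all orders agree on trend-free
noise).  The default grid is ~20 log-spaced window sizes from 60 samples
(30 s at 0.5 s sampling) to N/4; beyond N/4 the estimate is statistically
unreliable.  The workflow scripts fit over 30 s–4.4 h, the scaling region
of interest for these records.

`select_scaling_range()` operationalizes the scaling-range criteria
(stable local slopes, small residuals): among contiguous runs of at least
6 window sizes whose running slopes (computed over a 3-point window;
adjacent-point slopes are too noisy at the largest windows, where only a
few segments contribute) all lie within 0.1 of their median, the longest
run wins, with SSR-per-point as tie-break; the coefficient of variation of
the local slopes is reported as a diagnostic rather than optimized, since
"maximum coefficient of variation" as a selection objective is
ill-posed.  A range that excludes the largest windows raises a crossover
flag.  If nothing qualifies, the full range is returned with a warning.

`moving_average_filter()` is the circadian control.  It estimates the
waveform of a rhythm at the filter period as the comb (seasonal) moving
average — the mean over samples one period apart — and returns the series
minus that estimate.  Any exactly periodic component at the filter period
(including a constant) is removed completely; fluctuations at other scales
pass through.  A plain centered moving average cannot do this: with a
window of exactly one period it returns a constant, leaving the rhythm in
the residual.  The default period of 23.5 h targets the circadian band
while avoiding exact commensurability with the 24 h component.  On
rhythm-plus-noise composites the exponent fitted over 30 s–4.4 h changes by
less than 0.05 after filtering and correlates above 0.9 with the unfiltered
exponent across animals.

## Bout statistics

`extract_events()` reads maximal runs of 0s (immobility) or 1s (mobility);
an immobility *event* must exceed 1 s.  Runs touching an excluded gap or
the record ends are censored — dropped, never bridged, since bridging would
fabricate long events across gaps.  `fdd_fit()` histograms the durations
(bins centered on multiples of the bin width, 1 s by default) and fits by
least squares either `log10(count)` vs `log10(duration)` (power law; the
slope is the scaling factor `S`) or `log10(count)` vs duration
(exponential), over 1–250 s by default to avoid the sparse tail.  Counts,
not densities, are fitted — so `S` depends on the bin width, which is
always recorded alongside it, and `bin_size_sensitivity()` makes that
dependence explicit, flagging bins wider than the mean event duration
where the regime changes.  Zero-count bins are excluded from the fit; with
~1e4 events this exclusion biases the fitted slope upward by a few
hundredths (tail bins that survive are the lucky ones), well inside the
±0.15 band the recovery tests use.  Maximum-likelihood power-law fitting
is deliberately out of scope: the regression-based `S` and its `r²` are
the quantities of interest.  Randomizing the series (a uniform permutation
of samples, preserving the value multiset) destroys the bout structure;
the shuffled control is then better fit by the exponential than by the
power law.

## The synthetic generator

`gen_fractal_locomotion()` builds a binary record as an alternating
renewal process, a route chosen over thresholding a continuous signal
because it gives *exact* control of the immobile-bout duration law:

* immobile bouts are drawn from a discrete power law with exponent −1.5 on
  1–250 s (0.5 s grid) — the exponent and truncation mirror the bout
  statistics the events module is designed to recover;
* mobile bouts are geometric with a time-varying mean, modulated through a
  logistic link by the rhythm mixture plus scaled long-range-correlated
  noise, calibrated so the realized time fraction ambulating matches
  `mean_activity`;
* the noise is spectrally synthesized Gaussian noise shaped to
  `f^-(2*alpha-1)` (`gen_fgn()`); spectral synthesis was chosen over
  circulant embedding for simplicity — it is exact in expectation and
  amply accurate at the ±0.05 exponent tolerance the estimator tests use;
* a smooth random across-day drift (random-phase components at the record
  length and its half, amplitude `trend_amplitude`) emulates the slow
  nonstationarity of real multi-day records — real activity means drift
  across days, which is also why order-3 detrending is the DFA default.

Default conditions: the full rhythm set (24, 12, 8, 6, 4.8, 4 h) with
logistic-scale amplitudes 1.2, 0.6, 0.45, 0.4, 0.35, 0.3; 6.5 days at
0.5 s; noise exponent 0.85; mean activity 0.25.  The rhythm amplitudes and
phases of real animals are unknown (free parameters); these defaults were
chosen once so that the realized records look like home-cage quail
records: hourly ambulation spanning roughly 5–45% around a ~25% mean with
a strong day-night contrast, tens of thousands of immobility events per
week with means near 18 s.  The circadian amplitude dominates, and the
ultradian amplitudes are strong enough for spectral detection while —
deliberately — not so strong that every method flags every rhythm (in the
target system the 12 h Enright peak is significant only in a minority of
animals).

What the generator does *not* emulate: behavioral state switching beyond
two states, feeding-schedule entrainment, social coupling, measurement
artifacts of video tracking, and the exact transfer of the modulation
noise exponent through the binary channel — the realized DFA exponent of
the binary record is somewhat below the modulation target (e.g. ~0.76–0.79
measured over 30 s–4.4 h for a target of 0.85, comfortably inside the range
observed in real birds).  Tests passing on these synthetics therefore
demonstrate that the estimators recover what the generator put in, not
that real data satisfy the generator's assumptions.

## Numerical choices and degenerate inputs

* Constant series: the spectrum is flagged and zero, DFA and the Enright
  statistic raise errors (variance-normalized statistics are undefined).
* Spearman correlations are computed on ranks; with ties, self-correlation
  can differ from 1 by floating-point epsilon — consumers should compare
  with tolerance.
* The Fourier frequency grid of a 6.5-day record quantizes periods: a 24 h
  tone lands on the 6- or 7-cycle ordinate (26.0 or 22.3 h); peak-location
  assertions use one-frequency-bin tolerance.
* Trial periods, scales and window sizes are integers (bins/samples);
  "multiple of" comparisons use half-bin tolerance.
* All generators are reproducible given their seed, and restore the
  caller's RNG state.

## Problem sizes used by the checks

The end-to-end checks run at the study's own geometry where that is cheap
(6.5-day records, 1560 six-minute bins, scales 1–400, DFA at n = 2^17,
1000-replicate null calibrations) and at reduced flock sizes (3–12
synthetic animals) where a full cohort would add runtime without adding
information.  The workflow scripts state their sizes inline.

## Known limitations

* The Enright chi-square reference is conservative for trial periods
  folded into few blocks; significance near N/2 should be read with care.
* The IMF count of a 6.5-day record sits at the boundary of the
  dyadic-filter-bank expectation (~14); synthetic animals occasionally
  yield 12–13 modes where real records are reported at 14–15.
* Synchrony at scales beyond a few hours has few effective samples per
  pair on a week-long record; only the pair-averaged profile is
  interpretable there.
* The power-law slope `S` is bin-width dependent by construction (counts
  are fitted); comparisons across studies must match bin widths.
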