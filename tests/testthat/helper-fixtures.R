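# shared fixture builders (all data is generated in code)

# a binary series with a given repeating pattern
pattern_series <- function(pattern, reps, dt = 0.5, ...) {
  locomotion_series(rep_len(rep(pattern, reps), length(pattern) * reps),
                    dt = dt, ...)
}

# sinusoidal "actogram" on a 6-min grid: baseline + components, small noise
sine_actogram <- function(periods_h, amplitudes = 10, phases = 0,
                          days = 6.5, bin_seconds = 360, baseline = 30,
                          noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- floor(days * 86400 / bin_seconds)
  t_h <- (seq_len(n) - 1) * bin_seconds / 3600
  amplitudes <- rep_len(amplitudes, length(periods_h))
  phases <- rep_len(phases, length(periods_h))
  x <- baseline
  for (i in seq_along(periods_h))
    x <- x + amplitudes[i] * sin(2 * pi * t_h / periods_h[i] + phases[i])
  if (noise_sd > 0) x <- x + rnorm(n, sd = noise_sd)
  actogram(pmin(100, pmax(0, x)), bin_seconds = bin_seconds)
}

# hand-built Enright result for testing the peak-selection rule: a full
# trial-period axis with unit baseline and spikes at the given periods
fake_enright <- function(peak_bins, peak_qp, axis = 2:400,
                         bin_seconds = 360) {
  qp <- rep(1, length(axis))
  qp[match(peak_bins, axis)] <- peak_qp
  structure(list(periods_hours = axis * bin_seconds / 3600,
                 period_bins = axis, qp = qp, power = qp,
                 scores = qp, method = "enright",
                 significant = qp > 10,
                 alpha_level = 0.001, bin_seconds = bin_seconds,
                 n = 4 * max(axis)),
            class = "periodogram_result")
}

# hand-built DFA result with a prescribed fluctuation function
fake_dfa <- function(window_sizes, fluctuations, order = 3) {
  structure(list(window_sizes = window_sizes, fluctuations = fluctuations,
                 order = order, dt = NA_real_, n = 4 * max(window_sizes),
                 alpha = NA_real_, fit_range = range(window_sizes),
                 r_squared = NA_real_,
                 local_slopes = diff(log(fluctuations)) /
                   diff(log(window_sizes))),
            class = "dfa_result")
}

# hand-built Fourier periodogram with single spectral peaks (for the
# principal-peak rule)
fake_psa <- function(peak_period_h, periods_h = exp(seq(log(0.1), log(80),
                                                        length.out = 200)),
                     peak_power = 10, floor_power = 0.01) {
  pw <- rep(floor_power, length(periods_h))
  pw[which.min(abs(periods_h - peak_period_h))] <- peak_power
  structure(list(periods_hours = periods_h,
                 frequency_hz = 1 / (periods_h * 3600), power = pw,
                 method = "fourier", significant = rep(NA, length(pw)),
                 alpha_level = NA_real_, constant = FALSE,
                 dt = 30, n = 2 * length(pw)),
            class = "periodogram_result")
}
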