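# Run code with a locally scoped RNG state: restores .Random.seed on exit so
# generators are reproducible without clobbering the caller's stream.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Rhythm components
#'
#' A data frame of sinusoidal rhythm components: `period` in hours,
#' dimensionless `amplitude`, `phase` in radians.
#'
#' @param period periods in hours (> 0).
#' @param amplitude amplitudes (>= 0), recycled.
#' @param phase phases in radians, recycled.
#' @export
rhythm_components <- function(period, amplitude = 1, phase = 0) {
  if (any(period <= 0)) stop("periods must be positive")
  if (any(amplitude < 0)) stop("amplitudes must be non-negative")
  data.frame(period = period,
             amplitude = rep_len(amplitude, length(period)),
             phase = rep_len(phase, length(period)))
}

#' Sum-of-sines rhythm signal
#'
#' Deterministic superposition `s(t) = sum_k A_k sin(2 pi t / P_k + phi_k)`
#' sampled every `dt` seconds over `duration` days.  The canonical
#' validation construction is three equal-amplitude sines with periods 24,
#' 12 and 8 h over 6.5 days at 0.5 s sampling.
#'
#' @param components a [rhythm_components()] data frame.
#' @param duration duration in days.
#' @param dt sampling interval in seconds.
#' @return Numeric vector of length `floor(duration * 86400 / dt)`.
#' @export
gen_sum_of_sines <- function(components = rhythm_components(c(24, 12, 8)),
                             duration = 6.5, dt = 0.5) {
  if (nrow(components) == 0L) stop("component list is empty")
  if (any(components$period <= 0)) stop("zero or negative period")
  if (duration <= 0) stop("zero duration")
  n <- floor(duration * 86400 / dt)
  t_sec <- (seq_len(n) - 1) * dt
  s <- numeric(n)
  for (i in seq_len(nrow(components))) {
    p_sec <- components$period[i] * 3600
    s <- s + components$amplitude[i] *
      sin(2 * pi * t_sec / p_sec + components$phase[i])
  }
  s
}

#' Fractional Gaussian noise by spectral synthesis
#'
#' Generates a zero-mean, unit-variance Gaussian series whose power spectrum
#' is shaped as `f^-beta` with `beta = 2 * alpha_target - 1`, so that its
#' expected detrended-fluctuation scaling exponent is `alpha_target`
#' (alpha = 0.5 is white noise; 0.5 < alpha < 1 gives long-range positive
#' correlations).  A white complex Gaussian half-spectrum is shaped by
#' `f^(-beta/2)` and inverse-transformed with Hermitian symmetry.
#'
#' @param alpha_target target scaling exponent in \[0.5, 1.2\].
#' @param n series length (>= 1024).
#' @param seed integer seed; identical seeds give identical series.
#' @return Numeric vector of length `n` (mean 0, variance 1).
#' @export
gen_fgn <- function(alpha_target, n, seed = NULL) {
  if (n < 1024) stop("n too small for stable spectral shaping (need >= 1024)")
  if (alpha_target < 0.5 || alpha_target > 1.2)
    stop("alpha_target outside [0.5, 1.2]")
  beta <- 2 * alpha_target - 1
  with_local_seed(seed, {
    m <- n %/% 2
    f <- seq_len(m) / n
    amp <- f^(-beta / 2)
    z <- complex(real = stats::rnorm(m), imaginary = stats::rnorm(m)) *
      amp / sqrt(2)
    # Hermitian spectrum: X[1]=DC=0, X[k+1]=z[k], X[n-k+1]=Conj(z[k])
    spec <- complex(length.out = n)
    spec[1 + seq_len(m)] <- z
    if (n %% 2 == 0) spec[m + 1] <- complex(real = Re(z[m]) * sqrt(2),
                                            imaginary = 0)
    spec[n + 1 - seq_len(n - m - 1)] <- Conj(spec[1 + seq_len(n - m - 1)])
    x <- Re(stats::fft(spec, inverse = TRUE)) / n
    as.numeric(scale(x))
  })
}

#' Synthetic-series specification
#'
#' Bundles the parameters of [gen_fractal_locomotion()]: the rhythm mixture,
#' record geometry, the target long-range-correlation exponent of the
#' modulating noise, the immobility-bout power law, and the baseline
#' activity fraction.  Defaults reproduce the statistical structure the
#' analyses in this package assume: the full circadian + ultradian rhythm
#' set (24, 12, 8, 6, 4.8, 4 h) with amplitudes decreasing away from the
#' circadian component, 6.5 days at 0.5 s sampling, noise exponent 0.85,
#' and immobile-bout durations following a power law of slope -1.5 on
#' 1-250 s.
#'
#' @param components [rhythm_components()] data frame (amplitudes are in
#'   logistic (log-odds) units of the mobility-modulation signal).
#' @param duration days.
#' @param dt seconds.
#' @param alpha_target scaling exponent of the modulating noise, \[0.5, 1.2\].
#' @param immobility_slope power-law exponent of immobile-bout durations.
#' @param bout_range support of the immobile-bout law, seconds.
#' @param mean_activity baseline fraction of time ambulating, (0, 1).
#' @param noise_sd standard deviation of the noise term in logistic units.
#' @param trend_amplitude amplitude, in logistic units, of a smooth random
#'   across-day drift (random-phase components at the record length and its
#'   half), emulating the slow nonstationarity of real multi-day activity
#'   records; 0 disables it.
#' @param seed integer seed.
#' @export
synthetic_spec <- function(components = rhythm_components(
                             c(24, 12, 8, 6, 4.8, 4),
                             amplitude = c(1.2, 0.6, 0.45, 0.4, 0.35, 0.3)),
                           duration = 6.5, dt = 0.5,
                           alpha_target = 0.85,
                           immobility_slope = -1.5,
                           bout_range = c(1, 250),
                           mean_activity = 0.25,
                           noise_sd = 0.8,
                           trend_amplitude = 0.6,
                           seed = 1L) {
  if (duration <= 0) stop("duration must be positive")
  if (mean_activity <= 0 || mean_activity >= 1)
    stop("mean_activity must lie in (0, 1)")
  if (alpha_target < 0.5 || alpha_target > 1.2)
    stop("alpha_target outside [0.5, 1.2]")
  structure(list(components = components, duration = duration, dt = dt,
                 alpha_target = alpha_target,
                 immobility_slope = immobility_slope,
                 bout_range = bout_range,
                 mean_activity = mean_activity,
                 noise_sd = noise_sd,
                 trend_amplitude = trend_amplitude, seed = seed),
            class = "synthetic_spec")
}

#' Sample bout durations from a truncated discrete power law
#'
#' Durations are drawn on the grid `seq(range[1], range[2], by = resolution)`
#' seconds with probability proportional to `d^exponent`.
#'
#' @param n number of bouts.
#' @param exponent power-law exponent (e.g. -1.5).
#' @param range support in seconds.
#' @param resolution duration grid step in seconds.
#' @return Numeric vector of durations in seconds.
#' @export
rbout_powerlaw <- function(n, exponent = -1.5, range = c(1, 250),
                           resolution = 0.5) {
  d <- seq(range[1], range[2], by = resolution)
  p <- d^exponent
  sample(d, n, replace = TRUE, prob = p / sum(p))
}

#' Generate a synthetic binary locomotion series
#'
#' Builds a binary series as an alternating renewal process.  Immobile-bout
#' durations are drawn from a truncated discrete power law
#' (`immobility_slope` on `bout_range` seconds).  Mobile-bout durations are
#' geometric with a time-varying mean modulated through a logistic link by
#' the rhythm mixture plus scaled long-range-correlated noise
#' ([gen_fgn()] at `alpha_target`), calibrated so the realized fraction of
#' time ambulating matches `mean_activity`.  This construction gives an
#' exactly controllable immobile-bout duration law (which thresholding a
#' continuous signal would not), rhythms detectable by periodogram/wavelet
#' analysis, and long-range correlations in the activity record.
#'
#' @param spec a [synthetic_spec()].
#' @param ... metadata passed to [locomotion_series()].
#' @return A [locomotion_series()].
#' @export
gen_fractal_locomotion <- function(spec = synthetic_spec(), ...) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- floor(spec$duration * 86400 / spec$dt)
  d_grid <- seq(spec$bout_range[1], spec$bout_range[2], by = spec$dt)
  p_grid <- d_grid^spec$immobility_slope
  mean_immobile <- sum(d_grid * p_grid) / sum(p_grid)          # seconds
  odds <- spec$mean_activity / (1 - spec$mean_activity)
  mean_mobile <- odds * mean_immobile                          # seconds
  if (mean_mobile < spec$dt) {
    amin <- spec$dt / (spec$dt + mean_immobile)
    stop(sprintf(
      "mean_activity %.4f infeasible for this bout law; achievable range is roughly [%.4f, 1)",
      spec$mean_activity, amin))
  }
  with_local_seed(spec$seed, {
    # modulation signal on the sample grid (logistic / log-odds units)
    z <- numeric(n)
    if (nrow(spec$components) > 0 && any(spec$components$amplitude > 0))
      z <- z + gen_sum_of_sines(spec$components, spec$duration, spec$dt)
    ta <- spec$trend_amplitude %||% 0
    if (ta > 0) {
      # smooth random across-day drift: random-phase components at the
      # record length and its half (real multi-day records are
      # nonstationary; their mean drifts across days)
      drift <- rhythm_components(period = spec$duration * 24 / c(1, 2),
                                 amplitude = ta * c(1, 0.5),
                                 phase = stats::runif(2, 0, 2 * pi))
      z <- z + gen_sum_of_sines(drift, spec$duration, spec$dt)
    }
    if (spec$noise_sd > 0)
      z <- z + spec$noise_sd * gen_fgn(spec$alpha_target, n)
    g <- stats::plogis(z)
    g <- g / mean(g)                     # unit-mean multiplicative modulation
    # alternating renewal: pre-draw immobile bouts in bulk, draw each mobile
    # bout's geometric duration from the modulation at its start time
    exp_bouts <- ceiling(1.6 * n * spec$dt / (mean_immobile + mean_mobile)) + 16
    immobile_s <- sample(d_grid, exp_bouts, replace = TRUE,
                         prob = p_grid / sum(p_grid))
    lens <- integer(2 * exp_bouts)
    vals <- integer(2 * exp_bouts)
    pos <- 1L; i <- 0L; b <- 0L
    while (pos <= n) {
      b <- b + 1L
      if (b > length(immobile_s)) {      # top up in the rare shortfall case
        immobile_s <- c(immobile_s,
                        sample(d_grid, exp_bouts, replace = TRUE,
                               prob = p_grid / sum(p_grid)))
        lens <- c(lens, integer(2 * exp_bouts))
        vals <- c(vals, integer(2 * exp_bouts))
      }
      li <- max(1L, round(immobile_s[b] / spec$dt))
      i <- i + 1L; lens[i] <- li; vals[i] <- 0L
      pos <- pos + li
      if (pos > n) break
      m_t <- mean_mobile * g[pos] / spec$dt        # mean, in samples
      pr <- min(1, 1 / max(1, m_t))
      lm <- 1L + stats::rgeom(1L, pr)
      i <- i + 1L; lens[i] <- lm; vals[i] <- 1L
      pos <- pos + lm
    }
    x <- rep.int(vals[seq_len(i)], lens[seq_len(i)])[seq_len(n)]
    locomotion_series(x, dt = spec$dt, ...)
  })
}

#' Randomize (shuffle) a locomotion series
#'
#' Uniform random permutation of the non-excluded samples; the multiset of
#' values is preserved.  Shuffling destroys bout structure: a power-law
#' immobile-bout duration distribution becomes (geometric/) exponential,
#' the standard control for non-randomness of the bout law.
#'
#' @param series a [locomotion_series()].
#' @param seed integer seed.
#' @return A [locomotion_series()] with permuted values.
#' @export
randomize_series <- function(series, seed = NULL) {
  stopifnot(inherits(series, "locomotion_series"))
  with_local_seed(seed, {
    out <- series
    idx <- which(!series$excluded)
    out$values[idx] <- series$values[sample(idx)]
    out
  })
}
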