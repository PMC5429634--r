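# complex Morlet atom, cmorB-fc convention:
#   psi(t) = (pi*B)^(-1/2) * exp(2i*pi*fc*t) * exp(-t^2 / B)
cmor_psi <- function(t, bandwidth = 1, fc = 1.5) {
  (pi * bandwidth)^(-0.5) * exp(2i * pi * fc * t) * exp(-t^2 / bandwidth)
}

next_pow2 <- function(n) 2^ceiling(log2(n))

#' Continuous wavelet transform with a complex Morlet wavelet
#'
#' Convolves the mean-subtracted series with scaled complex Morlet atoms
#' (default `cmor1-1.5`: bandwidth 1, center frequency 1.5) at integer
#' scales, the standard setup for rhythm scalograms on 6-min actograms.
#' Scale `a` maps to period `a * bin_seconds / (3600 * fc)` hours, so with
#' 6-min bins and fc = 1.5, scales 1..400 cover periods 0.067 to 26.7 h.
#' The complex coefficients expose modulus, phase and real-part views; the
#' real part `Re(cwt)` localizes rhythm maxima in time.
#'
#' @param x an [actogram()] or a numeric vector sampled on a `bin_seconds`
#'   grid.
#' @param scales integer scales (default `1:400`).
#' @param bin_seconds grid step in seconds (taken from the actogram when one
#'   is supplied).
#' @param bandwidth Morlet bandwidth parameter (default 1).
#' @param fc Morlet center frequency (default 1.5).
#' @return A `wavelet_field`: list with complex `coefficients`
#'   (scales x time), `scales`, `periods_hours`, `bin_seconds`, `wavelet`,
#'   `animal_id`.
#' @export
cwt_morlet <- function(x, scales = 1:400, bin_seconds = NULL,
                       bandwidth = 1, fc = 1.5) {
  animal_id <- NA_character_
  if (inherits(x, "actogram")) {
    bin_seconds <- x$bin_seconds
    animal_id <- x$animal_id
    x <- x$percents
  }
  if (is.null(bin_seconds)) stop("bin_seconds required for numeric input")
  if (anyNA(x)) stop("missing values in series; interpolate or drop first")
  n <- length(x)
  if (n < 2 * max(scales))
    stop("max scale too large: series must be at least twice the max scale")
  xc <- x - mean(x)
  half_max <- ceiling(4 * sqrt(bandwidth / 2) * max(scales))
  L <- next_pow2(n + 2 * half_max + 1)
  X <- stats::fft(c(xc, rep(0, L - n)))
  coef <- matrix(0i, nrow = length(scales), ncol = n)
  for (si in seq_along(scales)) {
    a <- scales[si]
    half <- ceiling(4 * sqrt(bandwidth / 2) * a)
    tt <- (-half):half
    # correlation with the scaled atom: W(a,b) = sum_n x[n] h(n-b),
    # h(u) = a^(-1/2) Conj(psi(u/a)); realized as convolution with h(-u)
    ker <- Conj(cmor_psi(-tt / a, bandwidth, fc)) / sqrt(a)
    kp <- complex(length.out = L)
    kp[1:(half + 1)] <- ker[(half + 1):(2 * half + 1)]   # u = 0..half
    kp[(L - half + 1):L] <- ker[1:half]                  # u = -half..-1
    w <- stats::fft(X * stats::fft(kp), inverse = TRUE) / L
    coef[si, ] <- w[seq_len(n)]
  }
  structure(list(coefficients = coef, scales = scales,
                 periods_hours = scales * bin_seconds / (3600 * fc),
                 bin_seconds = bin_seconds,
                 wavelet = sprintf("cmor%g-%g", bandwidth, fc),
                 bandwidth = bandwidth, fc = fc, n = n,
                 animal_id = animal_id),
            class = "wavelet_field")
}

#' @export
print.wavelet_field <- function(x, ...) {
  cat(sprintf(
    "<wavelet_field> %s: %d scales x %d bins (%g s), periods %.3g-%.3g h\n",
    x$wavelet, length(x$scales), x$n, x$bin_seconds,
    min(x$periods_hours), max(x$periods_hours)))
  invisible(x)
}

# nearest scale row for a requested period (hours)
scale_row <- function(field, period_hours) {
  which.min(abs(field$periods_hours - period_hours))
}

# Local maxima of y with a prominence floor and a minimum separation.
# Prominence of a peak = its height minus the highest minimum one must
# descend to before reaching higher ground (or the series edge).
find_peaks <- function(y, min_prominence = 0, min_separation = 1) {
  cand <- local_maxima(y)
  if (length(cand) == 0L) return(integer())
  n <- length(y)
  prom <- vapply(cand, function(i) {
    h <- y[i]
    left_higher <- which(y[seq_len(i - 1)] > h)
    left <- if (length(left_higher)) min(y[max(left_higher):i]) else min(y[1:i])
    right_higher <- if (i < n) which(y[(i + 1):n] > h) + i else integer()
    right <- if (length(right_higher)) min(y[i:min(right_higher)])
             else min(y[i:n])
    h - max(left, right)
  }, numeric(1))
  keep <- cand[prom >= min_prominence]
  pr <- prom[prom >= min_prominence]
  # enforce minimum separation, keeping the taller peak
  ord <- keep[order(-y[keep])]
  sel <- integer()
  for (i in ord)
    if (all(abs(i - sel) >= min_separation)) sel <- c(sel, i)
  sort(sel)
}

#' Lag times between wavelet peaks at one scale
#'
#' Detects the prominent local maxima of `Re(cwt)` at the scale row nearest
#' the requested period, and returns the successive peak-to-peak intervals.
#' If a rhythm with that period is present, the mean lag approximates the
#' period itself, which is the analytical confirmation the lag plot
#' provides.  Peaks must have prominence of at least `prominence_frac` of
#' the row's range and be separated by at least half the period.
#'
#' @param field a `wavelet_field`.
#' @param period_hours time scale at which to detect peaks.
#' @param prominence_frac prominence floor as a fraction of the row's
#'   max-min range (default 0.1).
#' @param min_sep_frac minimum peak separation as a fraction of the period
#'   (default 0.5).
#' @return List with `peak_times_hours`, `lags_hours`, `mean_lag_hours`,
#'   `sem_lag_hours`, `n_peaks`, `period_hours` (the matched row period).
#' @export
peak_lag_times <- function(field, period_hours, prominence_frac = 0.1,
                           min_sep_frac = 0.5) {
  stopifnot(inherits(field, "wavelet_field"))
  if (period_hours < min(field$periods_hours) ||
      period_hours > max(field$periods_hours))
    stop("period outside the field's period range")
  row <- scale_row(field, period_hours)
  y <- Re(field$coefficients[row, ])
  period_bins <- field$periods_hours[row] * 3600 / field$bin_seconds
  pk <- find_peaks(y, min_prominence = prominence_frac * diff(range(y)),
                   min_separation = min_sep_frac * period_bins)
  if (length(pk) < 2L) stop("fewer than 2 peaks found at this scale")
  times_h <- (pk - 1) * field$bin_seconds / 3600
  lags <- diff(times_h)
  list(peak_times_hours = times_h, lags_hours = lags,
       mean_lag_hours = mean(lags),
       sem_lag_hours = stats::sd(lags) / sqrt(length(lags)),
       n_peaks = length(pk),
       period_hours = field$periods_hours[row])
}

#' Wavelet-based synchrony between two animals
#'
#' For each scale, the Spearman rank correlation over time between the real
#' wavelet coefficients of the two fields, excluding a cone-of-influence
#' margin of one period at each edge where coefficients are contaminated by
#' boundary effects.  Being rank-based, the profile is invariant to any
#' monotone per-scale normalization of the coefficients; it is symmetric in
#' its arguments and invariant to positive rescaling of either input.
#'
#' @param fieldA,fieldB `wavelet_field`s on identical scale/time grids.
#' @return A `synchrony_profile` data frame: `period_hours`, `rho`, with
#'   attribute `pair` naming the two animals.
#' @export
synchrony <- function(fieldA, fieldB) {
  stopifnot(inherits(fieldA, "wavelet_field"),
            inherits(fieldB, "wavelet_field"))
  if (!identical(fieldA$scales, fieldB$scales) ||
      fieldA$bin_seconds != fieldB$bin_seconds || fieldA$n != fieldB$n)
    stop("wavelet fields are on different grids")
  n <- fieldA$n
  rho <- vapply(seq_along(fieldA$scales), function(si) {
    coi <- ceiling(fieldA$periods_hours[si] * 3600 / fieldA$bin_seconds)
    if (n - 2 * coi < 8L) return(NA_real_)
    idx <- seq.int(coi + 1, n - coi)
    stats::cor(Re(fieldA$coefficients[si, idx]),
               Re(fieldB$coefficients[si, idx]), method = "spearman")
  }, numeric(1))
  out <- data.frame(period_hours = fieldA$periods_hours, rho = rho)
  attr(out, "pair") <- c(fieldA$animal_id, fieldB$animal_id)
  class(out) <- c("synchrony_profile", "data.frame")
  out
}

#' Group synchrony profile
#'
#' Mean and SEM of the pairwise synchrony correlation over all unordered
#' pairs of fields, per scale.
#'
#' @param fields list of >= 2 `wavelet_field`s on a common grid.
#' @return Data frame `period_hours`, `rho_mean`, `rho_sem`, `n_pairs`.
#' @export
group_synchrony <- function(fields) {
  if (length(fields) < 2L) stop("need at least 2 wavelet fields")
  pairs <- utils::combn(length(fields), 2)
  profs <- lapply(seq_len(ncol(pairs)), function(k)
    synchrony(fields[[pairs[1, k]]], fields[[pairs[2, k]]])$rho)
  m <- do.call(cbind, profs)
  data.frame(period_hours = fields[[1]]$periods_hours,
             rho_mean = rowMeans(m),
             rho_sem = apply(m, 1, stats::sd) / sqrt(ncol(m)),
             n_pairs = ncol(m))
}
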