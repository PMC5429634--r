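#' One-sided Fourier power spectrum
#'
#' Periodogram of a (mean-subtracted) series, normalized so that the sum of
#' the one-sided power ordinates equals the series variance (population
#' divisor): Parseval's identity.  Periods are reported in hours.
#'
#' @param x numeric vector, or a [locomotion_series()] / [actogram()]
#'   (its own sampling interval is then used and `dt` ignored).
#' @param dt sampling interval in seconds (for plain numeric input).
#' @return A `periodogram_result`: list with `periods_hours`,
#'   `frequency_hz`, `power`, `method = "fourier"`, `significant`,
#'   `alpha_level`, `constant` flag.
#' @export
power_spectrum <- function(x, dt = NULL) {
  if (inherits(x, "locomotion_series")) {
    dt <- x$dt
    x <- x$values[!x$excluded]
  } else if (inherits(x, "actogram")) {
    dt <- x$bin_seconds
    x <- x$percents
  }
  if (is.null(dt)) stop("dt required for plain numeric input")
  if (anyNA(x)) stop("missing values in series; interpolate or drop first")
  n <- length(x)
  if (n < 16L) stop("series too short for a spectrum (need >= 16 samples)")
  constant <- stats::var(x) == 0
  xc <- x - mean(x)
  X <- stats::fft(xc)
  m <- floor((n - 1) / 2)
  pw <- 2 * Mod(X[1 + seq_len(m)])^2 / n^2
  fr <- seq_len(m) / (n * dt)
  if (n %% 2 == 0) {
    pw <- c(pw, Mod(X[n / 2 + 1])^2 / n^2)
    fr <- c(fr, 1 / (2 * dt))
  }
  if (constant) warning("constant series: spectrum is identically zero")
  structure(list(periods_hours = 1 / fr / 3600, frequency_hz = fr,
                 power = pw, method = "fourier",
                 significant = rep(NA, length(pw)), alpha_level = NA_real_,
                 constant = constant, dt = dt, n = n),
            class = "periodogram_result")
}

#' @export
print.periodogram_result <- function(x, ...) {
  k <- which.max(x$power)
  cat(sprintf("<periodogram_result> %s: %d periods, peak at %.3g h%s\n",
              x$method, length(x$power), x$periods_hours[k],
              if (any(x$significant %in% TRUE))
                sprintf(" (%d significant at %g)",
                        sum(x$significant, na.rm = TRUE), x$alpha_level)
              else ""))
  invisible(x)
}

#' Flag significant spectral peaks
#'
#' Tests each periodogram ordinate against the white-noise null: for a
#' Gaussian white series the normalized ordinates `I_k / mean(I)` are
#' approximately unit-exponential, so `p_k = exp(-I_k / mean(I))`.  By
#' default each ordinate is tested at `alpha_level` (so on pure noise about
#' `alpha_level` of frequencies are flagged); `correction = "sidak"` applies
#' a Sidak family-wise correction across frequencies instead.
#'
#' @param result a Fourier `periodogram_result`.
#' @param alpha_level significance level (default 0.001).
#' @param correction `"none"` (per-frequency) or `"sidak"` (family-wise).
#' @return The result with `significant` and `alpha_level` filled in.
#' @export
peak_significance <- function(result, alpha_level = 0.001,
                              correction = c("none", "sidak")) {
  stopifnot(inherits(result, "periodogram_result"),
            result$method == "fourier")
  correction <- match.arg(correction)
  if (result$constant || all(result$power == 0)) {
    result$significant <- rep(FALSE, length(result$power))
    result$alpha_level <- alpha_level
    return(result)
  }
  pvals <- exp(-result$power / mean(result$power))
  thr <- if (correction == "sidak")
    1 - (1 - alpha_level)^(1 / length(pvals)) else alpha_level
  result$significant <- pvals < thr
  result$alpha_level <- alpha_level
  result$p_values <- pvals
  result
}

#' Spectral slope beta
#'
#' Least-squares slope of `log S(f)` vs `log f` over a period range; the
#' negated slope is the spectral exponent `beta` in `S(f) ~ f^-beta`.  For a
#' long-range-correlated series with scaling exponent `alpha`,
#' `beta = 2 * alpha - 1` (white noise: beta = 0).
#'
#' @param result a Fourier `periodogram_result`.
#' @param fit_range period interval in hours `c(min, max)` delimiting the
#'   frequencies used; default all resolved frequencies.
#' @return List with `beta`, `r_squared`, `n_freq`, `fit_range_hours`.
#' @export
spectral_slope <- function(result, fit_range = NULL) {
  stopifnot(inherits(result, "periodogram_result"),
            result$method == "fourier")
  keep <- result$power > 0
  if (!is.null(fit_range))
    keep <- keep & result$periods_hours >= fit_range[1] &
      result$periods_hours <= fit_range[2]
  if (sum(keep) < 10L)
    stop("fewer than 10 resolved frequencies inside fit_range")
  lf <- log(result$frequency_hz[keep])
  lp <- log(result$power[keep])
  fit <- stats::lm.fit(cbind(1, lf), lp)
  ssr <- sum(fit$residuals^2)
  r2 <- 1 - ssr / sum((lp - mean(lp))^2)
  list(beta = -unname(fit$coefficients[2]), r_squared = r2,
       n_freq = sum(keep),
       fit_range_hours = range(result$periods_hours[keep]))
}

#' Enright chi-square periodogram
#'
#' For each trial period `P` (in bins) the series is folded into blocks of
#' `P` points; if the true period is `P` the blocks are similar and the
#' variance of the per-phase column means is large relative to the total
#' variance.  The statistic is the Sokolove-Bushell normalization
#' `Q_P = N * var(column means) / var(series)` (population divisors, using
#' the `K = floor(N/P)` complete blocks), which under a noise null is
#' approximately chi-square with `P - 1` degrees of freedom; significance is
#' assessed at `alpha_level` from that distribution.  `Q_P` is invariant
#' under adding a constant to, or rescaling, the series.
#'
#' @param acto an [actogram()] (the standard input: 6-min-bin actograms
#'   reduce noise) or a plain numeric vector.
#' @param periods trial periods in bins; default `2:(N %/% 2)` (a one-bin
#'   period is degenerate and skipped).
#' @param alpha_level per-period significance level (default 0.001).
#' @return A `periodogram_result` with `method = "enright"`, plus
#'   `period_bins` and `qp`.
#' @export
enright_periodogram <- function(acto, periods = NULL, alpha_level = 0.001) {
  bin_seconds <- 1
  if (inherits(acto, "actogram")) {
    bin_seconds <- acto$bin_seconds
    x <- acto$percents
  } else x <- as.numeric(acto)
  if (anyNA(x)) stop("missing bins in actogram; interpolate or drop first")
  N <- length(x)
  if (is.null(periods)) periods <- 2:(N %/% 2)
  if (N < 2 * max(periods)) stop("series shorter than twice the max trial period")
  v <- mean((x - mean(x))^2)
  if (v == 0) stop("constant actogram: Q_P undefined")
  qp <- vapply(periods, function(P) {
    K <- N %/% P
    xt <- x[seq_len(K * P)]
    mh <- .rowMeans(matrix(xt, nrow = P), P, K)
    vt <- mean((xt - mean(xt))^2)
    (K * P) * mean((mh - mean(mh))^2) / vt
  }, numeric(1))
  sig <- qp > stats::qchisq(1 - alpha_level, df = periods - 1)
  structure(list(periods_hours = periods * bin_seconds / 3600,
                 period_bins = periods, qp = qp, power = qp,
                 scores = qp, method = "enright",
                 significant = sig, alpha_level = alpha_level,
                 bin_seconds = bin_seconds, n = N),
            class = "periodogram_result")
}

# indices of strict local maxima of y (plateaus: first index of the plateau)
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer())
  d <- diff(y)
  # treat zero steps by carrying the previous sign so plateaus count once
  s <- sign(d)
  for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  which(diff(s) < 0) + 1L
}

#' Sort Enright peaks and remove harmonics
#'
#' Applies the peak-selection rule used with the chi-square periodogram:
#' keep local maxima of `Q_P` exceeding 10% of the global maximum, sort
#' them in ascending period order, then remove every period that is an
#' integer multiple (within half a bin) of a retained shorter period,
#' since the periodogram cannot distinguish a rhythm from its harmonics.
#' When both a period and its multiple pass the threshold the shorter one
#' is kept (ascending-order processing).
#'
#' @param result an Enright `periodogram_result`.
#' @param threshold_frac fraction of the global maximum `Q_P` a local
#'   maximum must exceed (default 0.1).
#' @param tol_bins tolerance, in bins, for the integer-multiple test
#'   (default 0.5).
#' @return Data frame `period_bins`, `period_hours`, `qp`, `significant`,
#'   ascending in period.
#' @export
enright_select_peaks <- function(result, threshold_frac = 0.1,
                                 tol_bins = 0.5) {
  stopifnot(inherits(result, "periodogram_result"),
            result$method == "enright")
  pk <- local_maxima(result$qp)
  if (length(pk) == 0L) stop("no local maxima in periodogram")
  pk <- pk[result$qp[pk] > threshold_frac * max(result$qp)]
  ord <- pk[order(result$period_bins[pk])]
  kept <- integer()
  for (i in ord) {
    p <- result$period_bins[i]
    is_mult <- FALSE
    for (j in kept) {
      m <- p / result$period_bins[j]
      if (m >= 1.5 && abs(p - round(m) * result$period_bins[j]) <= tol_bins) {
        is_mult <- TRUE
        break
      }
    }
    if (!is_mult) kept <- c(kept, i)
  }
  data.frame(period_bins = result$period_bins[kept],
             period_hours = result$periods_hours[kept],
             qp = result$qp[kept],
             significant = result$significant[kept])
}
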