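#' Detrended fluctuation analysis
#'
#' Standard DFA: the mean-subtracted series is integrated into a profile,
#' the profile is partitioned into non-overlapping windows of size `n`
#' (both from the start and from the end, so the whole record contributes
#' when the length is not a multiple of `n`), each window is detrended with
#' a polynomial of the given order, and `F(n)` is the root-mean-square
#' residual.  The scaling exponent `alpha` is the least-squares slope of
#' `log F(n)` vs `log n` over the fit range: `alpha = 0.5` for an
#' uncorrelated series, `0.5 < alpha < 1` for long-range positive
#' correlations.  Order 3 detrending is the default, the lowest order that
#' removes slow (e.g. circadian) trends from week-long activity records.
#'
#' @param x numeric vector or a [locomotion_series()] (excluded samples are
#'   dropped and the series concatenated).
#' @param order detrending polynomial order (default 3).
#' @param window_sizes explicit window sizes in samples; by default ~20
#'   log-spaced sizes from `min_window` to `N/4` (estimates at the largest
#'   windows are noisy; beyond `N/4` they are unreliable).
#' @param min_window smallest window, in samples (default 60, i.e. 30 s at
#'   0.5 s sampling, clamped to at least `4 * (order + 2)`).
#' @param n_windows number of log-spaced window sizes (default 20).
#' @param fit_range `c(min, max)` window sizes (samples) used for the alpha
#'   fit; default the full grid.
#' @return A `dfa_result`: list with `window_sizes`, `fluctuations`,
#'   `order`, `alpha`, `fit_range`, `r_squared`, `local_slopes`, `n`.
#' @export
dfa <- function(x, order = 3L, window_sizes = NULL, min_window = 60L,
                n_windows = 20L, fit_range = NULL) {
  dt <- NA_real_
  if (inherits(x, "locomotion_series")) {
    dt <- x$dt
    x <- x$values[!x$excluded]
  }
  if (anyNA(x)) stop("missing values in series")
  N <- length(x)
  if (stats::var(x) == 0)
    stop("constant series: fluctuation function is identically zero")
  if (is.null(window_sizes)) {
    lo <- max(min_window, 4L * (order + 2L))
    hi <- N %/% 4L
    if (hi <= lo) stop("series too short for the requested window grid")
    window_sizes <- unique(round(exp(seq(log(lo), log(hi),
                                         length.out = n_windows))))
  }
  window_sizes <- sort(unique(as.integer(window_sizes)))
  if (N < 4L * max(window_sizes))
    stop("series shorter than 4x the largest window")
  y <- cumsum(x - mean(x))
  Fn <- vapply(window_sizes, function(n) {
    K <- N %/% n
    X <- outer(seq_len(n) / n, 0:order, `^`)
    qx <- qr(X)
    fwd <- matrix(y[seq_len(K * n)], nrow = n)
    rev_ <- matrix(y[N + 1 - rev(seq_len(K * n))], nrow = n)
    r1 <- qr.resid(qx, fwd)
    r2 <- qr.resid(qx, rev_)
    sqrt((sum(r1^2) + sum(r2^2)) / (2 * K * n))
  }, numeric(1))
  res <- structure(list(window_sizes = window_sizes, fluctuations = Fn,
                        order = order, dt = dt, n = N,
                        alpha = NA_real_, fit_range = NULL,
                        r_squared = NA_real_,
                        local_slopes = diff(log(Fn)) / diff(log(window_sizes))),
                   class = "dfa_result")
  dfa_refit(res, fit_range)
}

#' Refit the DFA scaling exponent over a window-size range
#'
#' @param result a `dfa_result`.
#' @param fit_range `c(min, max)` window sizes in samples; `NULL` uses all.
#' @return The `dfa_result` with `alpha`, `fit_range`, `r_squared` updated.
#' @export
dfa_refit <- function(result, fit_range = NULL) {
  stopifnot(inherits(result, "dfa_result"))
  keep <- rep(TRUE, length(result$window_sizes))
  if (!is.null(fit_range))
    keep <- result$window_sizes >= fit_range[1] &
      result$window_sizes <= fit_range[2]
  if (sum(keep) < 3L) stop("fewer than 3 window sizes in fit_range")
  ln <- log(result$window_sizes[keep])
  lf <- log(result$fluctuations[keep])
  fit <- stats::lm.fit(cbind(1, ln), lf)
  result$alpha <- unname(fit$coefficients[2])
  result$r_squared <- 1 - sum(fit$residuals^2) / sum((lf - mean(lf))^2)
  result$fit_range <- range(result$window_sizes[keep])
  result
}

#' @export
print.dfa_result <- function(x, ...) {
  cat(sprintf(
    "<dfa_result> DFA%d: alpha = %.3f (r2 = %.4f) over windows %d-%d of %d samples\n",
    x$order, x$alpha, x$r_squared, x$fit_range[1], x$fit_range[2], x$n))
  invisible(x)
}

#' Select the scaling range of a fluctuation function
#'
#' Operationalizes the scaling-range criteria (stable local slopes, small
#' fit residuals): among contiguous runs of at least `min_points` window
#' sizes whose adjacent-point local slopes all lie within `slope_tol` of
#' their median, the longest run is selected (ties broken by the smallest
#' linear-fit SSR per point).  The coefficient of variation of the local
#' slopes inside the selected range is reported as a diagnostic, and a
#' deviation flag is raised when the range excludes the largest windows
#' (a crossover, as seen in a minority of real records above ~4.4 h).
#' If no qualifying run exists the full range is returned with a warning.
#'
#' @param result a `dfa_result` with >= 10 window sizes.
#' @param slope_tol maximum deviation of local slopes from their median
#'   (default 0.1).
#' @param min_points minimum number of window sizes in a range (default 6).
#' @return List with `fit_range` (`c(min, max)` samples), `idx`, `flagged`
#'   (TRUE when the selected range ends before the largest window),
#'   `cv_local_slopes`, `qualified` (whether any run met the criteria).
#' @export
select_scaling_range <- function(result, slope_tol = 0.1, min_points = 6L) {
  stopifnot(inherits(result, "dfa_result"))
  ws <- result$window_sizes
  if (length(ws) < 10L) stop("need >= 10 window sizes")
  ln <- log(ws); lf <- log(result$fluctuations)
  n <- length(ws)
  # running slopes over a 3-point window: adjacent-point slopes are too
  # noisy at the largest windows (few segments) to judge stability
  ls <- vapply(seq_len(n - 1L), function(i) {
    idx <- max(1L, i - 1L):min(n, i + 2L)
    stats::cov(ln[idx], lf[idx]) / stats::var(ln[idx])
  }, numeric(1))
  best <- NULL
  for (i in seq_len(n - min_points + 1L)) {
    for (j in seq.int(i + min_points - 1L, n)) {
      sl <- ls[i:(j - 1L)]
      if (max(abs(sl - stats::median(sl))) > slope_tol) break
      fit <- stats::lm.fit(cbind(1, ln[i:j]), lf[i:j])
      ssr_pp <- sum(fit$residuals^2) / (j - i + 1L)
      len <- j - i + 1L
      if (is.null(best) || len > best$len ||
          (len == best$len && ssr_pp < best$ssr_pp))
        best <- list(i = i, j = j, len = len, ssr_pp = ssr_pp)
    }
  }
  if (is.null(best)) {
    warning("no window-size run satisfies the scaling criteria; returning full range")
    return(list(fit_range = range(ws), idx = seq_len(n), flagged = TRUE,
                cv_local_slopes = stats::sd(ls) / abs(mean(ls)),
                qualified = FALSE))
  }
  idx <- best$i:best$j
  sl <- ls[best$i:(best$j - 1L)]
  list(fit_range = c(ws[best$i], ws[best$j]), idx = idx,
       flagged = best$j < n,
       cv_local_slopes = stats::sd(sl) / abs(mean(sl)),
       qualified = TRUE)
}

#' Remove a periodic component with a comb moving average
#'
#' Estimates the waveform of a rhythm of the stated period by averaging the
#' series across repeats of that period (the mean over samples one period
#' apart, centered), and returns the series minus that estimate.  Any
#' component that is exactly periodic at the filter period (including a
#' constant) is removed completely, while fluctuations on other time
#' scales pass through; this is the control used to show that slow
#' circadian oscillations do not drive the fluctuation-analysis exponent.
#' The default period, 23.5 h, targets the circadian band.
#'
#' @param x numeric vector or [locomotion_series()].
#' @param period_hours filter period (default 23.5).
#' @param dt sampling interval in seconds (taken from a series input).
#' @return Numeric vector: the rhythm-removed residual, same length as the
#'   input.
#' @export
moving_average_filter <- function(x, period_hours = 23.5, dt = NULL) {
  if (inherits(x, "locomotion_series")) {
    dt <- x$dt
    x <- x$values[!x$excluded]
  }
  if (is.null(dt)) stop("dt required for numeric input")
  N <- length(x)
  Tn <- round(period_hours * 3600 / dt)
  if (Tn < 1L || Tn >= N) stop("filter period longer than the series")
  phase <- ((seq_len(N) - 1L) %% Tn) + 1L
  K <- ceiling(N / Tn)
  pad <- K * Tn - N
  m <- matrix(c(x, rep(NA_real_, pad)), nrow = Tn)
  wave <- rowMeans(m, na.rm = TRUE)
  x - wave[phase]
}
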