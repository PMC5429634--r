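#' Extract mobility / immobility bouts
#'
#' A bout is a maximal run of identical samples; its duration is the run
#' length times the sampling interval.  An immobility event is a run of 0s
#' strictly longer than 1 s (so at 0.5 s sampling, at least 3 samples); a
#' mobility event is any run of 1s.  Runs touching an excluded
#' (housekeeping) gap, or the ends of the record, are censored and dropped
#' rather than bridged, since their true duration is unknown.
#'
#' @param series a [locomotion_series()].
#' @param kind `"immobile"` or `"mobile"`.
#' @param min_duration minimum duration in seconds, exclusive; default
#'   1 s for immobility events, 0 for mobility events.
#' @return Numeric vector of durations in seconds, with attribute
#'   `n_censored` (number of dropped boundary runs).
#' @export
extract_events <- function(series, kind = c("immobile", "mobile"),
                           min_duration = NULL) {
  stopifnot(inherits(series, "locomotion_series"))
  kind <- match.arg(kind)
  if (is.null(min_duration)) min_duration <- if (kind == "immobile") 1 else 0
  target <- if (kind == "immobile") 0 else 1
  v <- series$values
  v[series$excluded] <- NA_real_
  # split into contiguous non-excluded segments
  seg_id <- cumsum(c(TRUE, diff(is.na(v)) != 0))
  durations <- numeric(0)
  n_censored <- 0L
  for (s in split(seq_along(v), seg_id)) {
    if (is.na(v[s[1]])) next
    r <- rle(v[s])
    keep <- r$values == target
    if (length(r$lengths) >= 1L) {
      # censor runs abutting the segment boundaries
      if (keep[1]) { keep[1] <- FALSE; n_censored <- n_censored + 1L }
      k <- length(keep)
      if (k > 1L && r$values[k] == target && keep[k]) {
        keep[k] <- FALSE; n_censored <- n_censored + 1L
      }
    }
    durations <- c(durations, r$lengths[keep] * series$dt)
  }
  out <- durations[durations > min_duration]
  attr(out, "n_censored") <- n_censored
  out
}

#' Full bout table (for conservation checks and event exports)
#'
#' @param series a [locomotion_series()].
#' @return Data frame `start_s`, `duration_s`, `kind`, `censored` covering
#'   every non-excluded run.
#' @export
bout_table <- function(series) {
  stopifnot(inherits(series, "locomotion_series"))
  v <- series$values
  v[series$excluded] <- NA_real_
  seg_id <- cumsum(c(TRUE, diff(is.na(v)) != 0))
  rows <- lapply(split(seq_along(v), seg_id), function(s) {
    if (is.na(v[s[1]])) return(NULL)
    r <- rle(v[s])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cens <- seq_along(r$lengths) %in% c(1L, length(r$lengths))
    data.frame(start_s = (s[1] - 1L + starts - 1L) * series$dt,
               duration_s = r$lengths * series$dt,
               kind = ifelse(r$values == 1, "mobile", "immobile"),
               censored = cens)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit the frequency distribution of bout durations
#'
#' Histograms the durations at `bin_seconds` resolution (bins centered on
#' multiples of the bin width) and fits, by least squares over the
#' non-empty bins inside `fit_range`:
#' * `"power_law"`: `log10(frequency)` vs `log10(duration)`; the slope is
#'   the scaling factor `S` (a linear log-log plot indicates a fractal,
#'   power-law bout distribution);
#' * `"exponential"`: `log10(frequency)` vs `duration`; the slope is the
#'   (base-10) decay rate, the expected form for randomized data.
#'
#' Frequencies are raw counts, not densities, so `S` depends on the bin
#' width; the bin width is always recorded alongside `S`.  The default fit
#' range 1-250 s avoids the sparse tail of the distribution.
#'
#' @param durations numeric vector of durations in seconds (>= 50 events).
#' @param bin_seconds histogram bin width (default 1).
#' @param fit_range `c(min, max)` durations in seconds used for the fit.
#' @param fit_kind `"power_law"` or `"exponential"`.
#' @return An `event_distribution`: list with `durations`, `bin_seconds`,
#'   `hist` (data frame `duration_s`, `frequency`), `fit_kind`, `slope_S`,
#'   `intercept`, `r_squared`, `fit_range`, `n_events`, `n_bins_fit`.
#' @export
fdd_fit <- function(durations, bin_seconds = 1, fit_range = c(1, 250),
                    fit_kind = c("power_law", "exponential")) {
  fit_kind <- match.arg(fit_kind)
  durations <- as.numeric(durations)
  if (length(durations) < 50L) stop("need at least 50 events to fit")
  if (fit_range[1] < min(durations) - bin_seconds / 2 &&
      fit_range[2] < min(durations))
    stop("fit_range lies outside the observed durations")
  centers_all <- seq(bin_seconds, max(durations) + bin_seconds,
                     by = bin_seconds)
  breaks <- c(centers_all - bin_seconds / 2,
              centers_all[length(centers_all)] + bin_seconds / 2)
  counts <- graphics::hist(durations[durations >= breaks[1]],
                           breaks = breaks, plot = FALSE)$counts
  hist_df <- data.frame(duration_s = centers_all, frequency = counts)
  sel <- counts > 0 & centers_all >= fit_range[1] &
    centers_all <= fit_range[2]
  if (sum(sel) < 2L) stop("fewer than 2 non-empty bins inside fit_range")
  xx <- if (fit_kind == "power_law") log10(centers_all[sel])
        else centers_all[sel]
  yy <- log10(counts[sel])
  if (stats::var(xx) == 0) stop("degenerate histogram: single occupied bin")
  fit <- stats::lm.fit(cbind(1, xx), yy)
  r2 <- 1 - sum(fit$residuals^2) / sum((yy - mean(yy))^2)
  structure(list(durations = durations, bin_seconds = bin_seconds,
                 hist = hist_df, fit_kind = fit_kind,
                 slope_S = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1]),
                 r_squared = r2, fit_range = fit_range,
                 n_events = length(durations), n_bins_fit = sum(sel)),
            class = "event_distribution")
}

#' @export
print.event_distribution <- function(x, ...) {
  cat(sprintf(
    "<event_distribution> %s fit: slope S = %.3f (r2 = %.3f), %d events, %g s bins, fit on %g-%g s\n",
    x$fit_kind, x$slope_S, x$r_squared, x$n_events, x$bin_seconds,
    x$fit_range[1], x$fit_range[2]))
  invisible(x)
}

#' Bin-size sensitivity of the duration-distribution fit
#'
#' Repeats [fdd_fit()] across a grid of histogram bin widths.  The fitted
#' slope depends on bin size (frequencies are counts), and bins wider than
#' the mean event duration change the regime of the fit; such rows are
#' flagged.
#'
#' @param durations numeric vector of durations in seconds.
#' @param bin_grid bin widths in seconds (default
#'   `c(0.5, 1, 5, 10, 30, 60)`).
#' @param fit_range passed to [fdd_fit()].
#' @param fit_kind fit kinds to evaluate (default both).
#' @return Data frame `bin_seconds`, `fit_kind`, `S`, `r_squared`,
#'   `beyond_mean_duration`.
#' @export
bin_size_sensitivity <- function(durations,
                                 bin_grid = c(0.5, 1, 5, 10, 30, 60),
                                 fit_range = c(1, 250),
                                 fit_kind = c("power_law", "exponential")) {
  if (length(bin_grid) == 0L) stop("bin_grid is empty")
  mean_dur <- mean(durations)
  rows <- lapply(bin_grid, function(b) {
    do.call(rbind, lapply(fit_kind, function(k) {
      f <- fdd_fit(durations, bin_seconds = b, fit_range = fit_range,
                   fit_kind = k)
      data.frame(bin_seconds = b, fit_kind = k, S = f$slope_S,
                 r_squared = f$r_squared,
                 beyond_mean_duration = b > mean_dur)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
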