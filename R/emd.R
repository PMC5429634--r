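# --- extrema and envelopes ---------------------------------------------------

# strict local extrema; plateaus contribute their first sample
find_extrema <- function(x) {
  list(max = local_maxima(x), min = local_maxima(-x))
}

# Natural cubic-spline envelope through extrema, with mirror extension of up
# to `n_mirror` extrema at each end to suppress end swings that would
# otherwise corrupt the slow modes of a multi-day record.
envelope_spline <- function(idx, val, n, n_mirror = 2L) {
  k <- length(idx)
  xs <- idx; ys <- val
  nm <- min(n_mirror, k)
  if (nm >= 1L) {
    xs <- c(2 - rev(idx[seq_len(nm)]), xs,
            2 * n - rev(idx[k - seq_len(nm) + 1L]))
    ys <- c(rev(val[seq_len(nm)]), ys, rev(val[k - seq_len(nm) + 1L]))
  }
  keep <- !duplicated(xs)
  stats::spline(xs[keep], ys[keep], xout = seq_len(n),
                method = "natural")$y
}

count_zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  sum(diff(s) != 0)
}

# --- sifting -----------------------------------------------------------------

#' Empirical mode decomposition
#'
#' Decomposes a series into intrinsic mode functions (IMFs) by classic
#' sifting: cubic-spline envelopes through the local maxima and minima
#' (natural splines, mirror boundary extension), subtraction of the envelope
#' mean, iterated until a stopping criterion holds and the counts of extrema
#' and zero crossings differ by at most one.  The default stopping rule is
#' the Rilling envelope-mean criterion (the default of the classic
#' open-source EMD toolbox): sifting continues while the relative envelope
#' mean `|mean(up, lo)| / amplitude` exceeds `theta1` on more than
#' `alpha_tol` of the record or exceeds `theta2` anywhere.
#' `stop_rule = "sd"` instead uses the Huang SD criterion
#' `mean((h_prev - h)^2 / h_prev^2) < sd_thresh`.  Decomposition stops when
#' the residual is monotonic or has fewer than two maxima or minima.
#' The signal is processed as-is: no detrending or denoising beforehand.
#'
#' IMFs are ordered fast to slow, and the decomposition is complete: the sum
#' of all IMFs plus the residual reconstructs the input to floating-point
#' accuracy.
#'
#' @param x numeric vector (length >= 8, with at least 2 maxima and 2
#'   minima), or an [actogram()] (its percents are decomposed; the standard
#'   choice upstream of per-mode spectra is a 30 s-bin actogram).
#' @param stop_rule `"rilling"` (default) or `"sd"`.
#' @param theta1,theta2,alpha_tol Rilling criterion parameters (defaults
#'   0.05, 0.5, 0.05).
#' @param sd_thresh Huang SD stopping threshold (default 0.2).
#' @param max_sift per-IMF sifting iteration cap (default 200).
#' @param max_imfs optional cap on the number of IMFs.
#' @return An `imf_set`: list with `imfs` (list of numeric vectors, fast to
#'   slow), `residual`, `n_sift_iters`, `input`.
#' @export
emd_decompose <- function(x, stop_rule = c("rilling", "sd"),
                          theta1 = 0.05, theta2 = 0.5, alpha_tol = 0.05,
                          sd_thresh = 0.2, max_sift = 200L,
                          max_imfs = Inf) {
  stop_rule <- match.arg(stop_rule)
  bin_seconds <- NA_real_
  if (inherits(x, "actogram")) {
    bin_seconds <- x$bin_seconds
    x <- x$percents
  }
  if (anyNA(x)) stop("missing values in series")
  n <- length(x)
  if (n < 8L) stop("series too short for EMD")
  input <- x
  imfs <- list()
  iters <- integer()
  repeat {
    ex <- find_extrema(x)
    # continue while the residual still oscillates: >= 3 extrema in total
    if (length(ex$max) + length(ex$min) < 3L || length(ex$max) < 1L ||
        length(ex$min) < 1L || length(imfs) >= max_imfs)
      break
    h <- x
    it <- 0L
    repeat {
      it <- it + 1L
      exh <- find_extrema(h)
      if (length(exh$max) + length(exh$min) < 3L || length(exh$max) < 1L ||
          length(exh$min) < 1L) break
      up <- envelope_spline(exh$max, h[exh$max], n)
      lo <- envelope_spline(exh$min, h[exh$min], n)
      m <- (up + lo) / 2
      stop_ok <- if (stop_rule == "rilling") {
        sigma <- abs(m) / pmax((up - lo) / 2, .Machine$double.eps)
        mean(sigma > theta1) <= alpha_tol && all(sigma <= theta2)
      } else {
        h_new <- h - m
        mean((h - h_new)^2 / (h^2 + .Machine$double.eps)) < sd_thresh
      }
      h <- h - m
      if (it >= max_sift) break
      if (stop_ok) {
        nex <- length(find_extrema(h)$max) + length(find_extrema(h)$min)
        if (abs(nex - count_zero_crossings(h)) <= 1L) break
      }
    }
    imfs[[length(imfs) + 1L]] <- h
    iters <- c(iters, it)
    x <- x - h
  }
  structure(list(imfs = imfs, residual = x, n_sift_iters = iters,
                 input = input, bin_seconds = bin_seconds),
            class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %d IMFs over %d samples (sift iters: %s)\n",
              length(x$imfs), length(x$residual),
              paste(x$n_sift_iters, collapse = ",")))
  invisible(x)
}

#' Power spectra of intrinsic mode functions
#'
#' Applies [power_spectrum()] to each IMF and records its dominant period.
#'
#' @param imfset an `imf_set` from [emd_decompose()].
#' @param dt sampling interval of the decomposed series in seconds (for an
#'   actogram input this is its bin width and may be omitted).
#' @return List of `periodogram_result`, each with attribute
#'   `dominant_period_hours`.
#' @export
imf_spectra <- function(imfset, dt = NULL) {
  stopifnot(inherits(imfset, "imf_set"))
  if (length(imfset$imfs) == 0L) stop("no IMFs to analyze")
  if (is.null(dt)) dt <- imfset$bin_seconds
  if (is.na(dt)) stop("dt required (series was not an actogram)")
  lapply(imfset$imfs, function(h) {
    ps <- power_spectrum(h, dt = dt)
    attr(ps, "dominant_period_hours") <- ps$periods_hours[which.max(ps$power)]
    ps
  })
}

# peaks of one PSA above a fraction of its maximum: (period, power) pairs
psa_peaks <- function(ps, height_frac = 0.3) {
  pk <- local_maxima(ps$power)
  # the first ordinate (longest period) can be a one-sided maximum
  if (length(ps$power) >= 2 && ps$power[1] > ps$power[2]) pk <- c(1L, pk)
  pk <- pk[ps$power[pk] > height_frac * max(ps$power)]
  data.frame(period_hours = ps$periods_hours[pk], power = ps$power[pk])
}

#' Principal spectral peaks of an IMF subgroup
#'
#' Implements the principal-peak histogram rule: within a contiguous
#' subgroup of `subgroup_size` IMFs, collect from each mode's power spectrum
#' the local maxima exceeding `height_frac` (default 30%) of that spectrum's
#' highest peak, and keep the `top_n` (default 10) largest of the pooled
#' peaks.  The subgroup defaults to the contiguous window of
#' `subgroup_size` IMFs whose dominant periods best cover the circadian to
#' 4 h band, mirroring the slow-mode window used for rhythm attribution.
#'
#' @param spectra list of `periodogram_result` from [imf_spectra()].
#' @param subgroup_size number of contiguous IMFs in the window (default 4).
#' @param imf_window integer indices of the window; `NULL` selects it
#'   automatically as above.
#' @param top_n number of pooled peaks retained.
#' @param height_frac per-spectrum peak height threshold fraction.
#' @return Data frame `period_hours`, `power`, `imf` (descending power).
#' @export
principal_peaks <- function(spectra, subgroup_size = 4L, imf_window = NULL,
                            top_n = 10L, height_frac = 0.3) {
  if (length(spectra) < subgroup_size)
    stop("need at least ", subgroup_size, " IMF spectra")
  if (is.null(imf_window)) {
    dom <- vapply(spectra, function(ps)
      ps$periods_hours[which.max(ps$power)], numeric(1))
    # window scoring: dominant periods inside the 3-30 h rhythm band
    starts <- seq_len(length(spectra) - subgroup_size + 1L)
    score <- vapply(starts, function(s) {
      d <- dom[s:(s + subgroup_size - 1L)]
      sum(d >= 3 & d <= 30)
    }, numeric(1))
    s0 <- starts[which.max(score)]
    imf_window <- s0:(s0 + subgroup_size - 1L)
  }
  pk <- do.call(rbind, lapply(imf_window, function(i) {
    d <- psa_peaks(spectra[[i]], height_frac)
    if (nrow(d)) d$imf <- i
    d
  }))
  if (is.null(pk) || nrow(pk) == 0L)
    return(data.frame(period_hours = numeric(), power = numeric(),
                      imf = integer()))
  pk <- pk[order(-pk$power), , drop = FALSE]
  pk <- utils::head(pk, top_n)
  rownames(pk) <- NULL
  pk
}

#' Histogram of principal peak periods across series
#'
#' Aggregates [principal_peaks()] results from several animals/series into
#' a period histogram, grouping periods into bins (default 1 h wide,
#' centered on integer hours, with sub-hour periods grouped at 0.5 h
#' resolution).
#'
#' @param peak_list list of data frames from [principal_peaks()].
#' @param digits rounding (in hours) used to group periods.
#' @return Data frame `period_hours`, `count`, descending count.
#' @export
peak_histogram <- function(peak_list, digits = 0.5) {
  p <- unlist(lapply(peak_list, function(d) d$period_hours))
  if (length(p) == 0L) return(data.frame(period_hours = numeric(),
                                         count = integer()))
  grp <- round(p / digits) * digits
  tb <- sort(table(grp), decreasing = TRUE)
  data.frame(period_hours = as.numeric(names(tb)),
             count = as.integer(tb), row.names = NULL)
}
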