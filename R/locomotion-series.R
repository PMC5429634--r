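#' Construct a locomotion series
#'
#' A `locomotion_series` is a uniformly sampled binary activity record: one
#' value per sampling interval, 1 if the animal was ambulating during the
#' interval and 0 if it was immobile.  The study design this package targets
#' records one sample every 0.5 s over ~6.5 days (~1.07e6 samples per
#' animal).
#'
#' Samples falling in housekeeping gaps (cage maintenance) can be marked in
#' `excluded`; excluded samples are dropped and the series is analyzed as if
#' concatenated, which is valid for the fluctuation analyses used here up to
#' large data-loss fractions.  An excluded fraction of 0.65 or more is
#' rejected.
#'
#' @param values integer or numeric vector of 0/1 activity samples.
#' @param dt sampling interval in seconds (default 0.5).
#' @param start_clock clock time of the first sample, `"HH:MM"` (default
#'   `"13:00"`, i.e. recordings starting at 1 PM).
#' @param photoperiod character vector `c(lights_on, lights_off)` clock times.
#' @param excluded logical vector marking housekeeping-gap samples, or `NULL`.
#' @param animal_id optional label.
#' @return An object of class `locomotion_series`: a list with elements
#'   `values`, `dt`, `start_clock`, `photoperiod`, `excluded`, `animal_id`.
#' @export
locomotion_series <- function(values, dt = 0.5, start_clock = "13:00",
                              photoperiod = c("06:00", "20:00"),
                              excluded = NULL, animal_id = NA_character_) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("empty series")
  if (anyNA(values) || !all(values %in% c(0, 1)))
    stop("locomotion values must all be 0 or 1")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("dt must be a positive scalar (seconds)")
  if (is.null(excluded)) excluded <- rep(FALSE, length(values))
  excluded <- as.logical(excluded)
  if (length(excluded) != length(values))
    stop("excluded mask must match series length")
  frac <- mean(excluded)
  if (frac >= 0.65)
    stop("excluded fraction ", signif(frac, 3),
         " >= 0.65; scaling analyses are not reliable beyond that data loss")
  structure(list(values = values, dt = dt, start_clock = start_clock,
                 photoperiod = photoperiod, excluded = excluded,
                 animal_id = animal_id),
            class = "locomotion_series")
}

#' @export
print.locomotion_series <- function(x, ...) {
  days <- length(x$values) * x$dt / 86400
  cat(sprintf(
    "<locomotion_series> %s: %d samples @ %.3g s (%.2f days), %.1f%% active, %.2f%% excluded\n",
    x$animal_id, length(x$values), x$dt, days,
    100 * mean(x$values[!x$excluded]), 100 * mean(x$excluded)))
  invisible(x)
}

#' @export
length.locomotion_series <- function(x) length(x$values)

#' Read a binary locomotion series from a text file
#'
#' Reads deposited-format series: one numeric sample per line, or a delimited
#' table with the activity samples in one column (select with `column`).
#' Values must all be 0 or 1; any other token is an error naming the
#' offending line.
#'
#' @param path file path.
#' @param dt sampling interval in seconds.
#' @param column column index holding the activity samples (for delimited
#'   files with a time or index column); default 1.
#' @param sep field separator; `""` (whitespace/one-per-line) or e.g. `","`.
#' @param header does the file have a header row?
#' @param ... further metadata passed to [locomotion_series()]
#'   (`start_clock`, `photoperiod`, `animal_id`, `excluded`).
#' @return A [locomotion_series()].
#' @export
read_locomotion <- function(path, dt = 0.5, column = 1L, sep = "",
                            header = FALSE, ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) stop("empty file: ", path)
  dat <- utils::read.table(path, sep = sep, header = header,
                           colClasses = "character",
                           blank.lines.skip = FALSE,
                           stringsAsFactors = FALSE)
  if (nrow(dat) == 0L) stop("empty file: ", path)
  if (column > ncol(dat)) stop("column ", column, " not present in ", path)
  tok <- trimws(dat[[column]])
  val <- suppressWarnings(as.numeric(tok))
  bad <- which(is.na(val) | !(val %in% c(0, 1)))
  if (length(bad)) {
    line <- bad[1] + as.integer(header)
    stop(sprintf("non-binary token %s at line %d of %s",
                 dQuote(tok[bad[1]]), line, path))
  }
  locomotion_series(val, dt = dt, ...)
}

#' Write a locomotion series in the one-sample-per-line text format
#'
#' @param series a [locomotion_series()].
#' @param path output file path.
#' @export
write_locomotion <- function(series, path) {
  stopifnot(inherits(series, "locomotion_series"))
  writeLines(format(as.integer(series$values)), path)
  invisible(path)
}

#' Hourly percent of time spent ambulating
#'
#' For each complete hour, the percentage of (non-excluded) intervals in
#' which the animal was ambulating: `Amb% = 100 * sum(x_i) / N`, with `N`
#' the number of retained intervals in the hour (7200 at dt = 0.5 s).
#'
#' @param series a [locomotion_series()].
#' @return Numeric vector, one value in \[0, 100\] per whole hour (`NA` for a
#'   fully excluded hour).  A trailing partial hour is dropped.
#' @export
percent_ambulating_hourly <- function(series) {
  stopifnot(inherits(series, "locomotion_series"))
  per_hour <- round(3600 / series$dt)
  n_hours <- length(series$values) %/% per_hour
  if (n_hours < 1L) stop("series shorter than one hour")
  idx <- seq_len(n_hours * per_hour)
  keep <- !series$excluded[idx]
  ones <- .colSums(series$values[idx] * keep, per_hour, n_hours)
  ns <- .colSums(as.numeric(keep), per_hour, n_hours)
  ifelse(ns > 0, 100 * ones / ns, NA_real_)
}

#' Bin a locomotion series into an actogram
#'
#' An actogram is the percent of time spent ambulating per bin; the standard
#' display bin here is 6 min (720 intervals at dt = 0.5 s), with 30 s bins
#' used upstream of empirical mode decomposition.
#'
#' Each bin's percent uses only its non-excluded samples; a fully excluded
#' bin is `NA` (missing), never 0.  A trailing partial bin is dropped.
#'
#' @param series a [locomotion_series()].
#' @param bin_seconds bin width in seconds; must be a multiple of `dt`.
#' @return An object of class `actogram`: list with `percents`,
#'   `bin_seconds`, `start_clock`, `day_length_bins`, `animal_id`.
#' @export
bin_to_actogram <- function(series, bin_seconds = 360) {
  stopifnot(inherits(series, "locomotion_series"))
  if (bin_seconds < series$dt) stop("bin_seconds smaller than dt")
  k <- bin_seconds / series$dt
  if (abs(k - round(k)) > 1e-9)
    stop("bin_seconds must be an integer multiple of dt")
  k <- round(k)
  n_bins <- length(series$values) %/% k
  if (n_bins < 1L) stop("series is shorter than one bin")
  idx <- seq_len(n_bins * k)
  keep <- !series$excluded[idx]
  ones <- .colSums(series$values[idx] * keep, k, n_bins)
  ns <- .colSums(as.numeric(keep), k, n_bins)
  pct <- ifelse(ns > 0, 100 * ones / ns, NA_real_)
  actogram(pct, bin_seconds = bin_seconds,
           start_clock = series$start_clock, animal_id = series$animal_id)
}

#' Construct an actogram object from binned percents
#'
#' @param percents numeric vector of percent-time-ambulating per bin (0-100,
#'   `NA` allowed for missing bins).
#' @param bin_seconds bin width in seconds.
#' @param start_clock clock time of the left edge of the first bin.
#' @param animal_id optional label.
#' @export
actogram <- function(percents, bin_seconds = 360, start_clock = "13:00",
                     animal_id = NA_character_) {
  percents <- as.numeric(percents)
  ok <- !is.na(percents)
  if (any(percents[ok] < 0 | percents[ok] > 100))
    stop("actogram percents must lie in [0, 100]")
  structure(list(percents = percents, bin_seconds = bin_seconds,
                 start_clock = start_clock,
                 day_length_bins = round(86400 / bin_seconds),
                 animal_id = animal_id),
            class = "actogram")
}

#' @export
print.actogram <- function(x, ...) {
  cat(sprintf("<actogram> %s: %d bins of %g s (%.2f days)\n",
              x$animal_id, length(x$percents), x$bin_seconds,
              length(x$percents) * x$bin_seconds / 86400))
  invisible(x)
}

#' Median actogram over one day
#'
#' Folds an actogram at the 24 h day length and takes the median percent at
#' each within-day bin position across days, ignoring missing bins.  Peaks
#' of the median day give visual evidence of ultradian (<24 h) rhythms.
#' Days are folded from the start of the record (first bin = day position 1).
#'
#' @param acto an [actogram()] spanning at least 2 full days.
#' @return Numeric vector of length `day_length_bins`.
#' @export
median_actogram <- function(acto) {
  stopifnot(inherits(acto, "actogram"))
  dlb <- acto$day_length_bins
  n_days <- length(acto$percents) %/% dlb
  if (n_days < 2L) stop("median actogram needs at least 2 full days")
  m <- matrix(acto$percents[seq_len(n_days * dlb)], nrow = dlb)
  apply(m, 1, stats::median, na.rm = TRUE)
}

#' Bin an arbitrary real-valued series by averaging
#'
#' Utility used to carry real-valued synthetic signals (e.g. rhythm
#' mixtures) onto the same bin grid as an actogram before spectral or
#' wavelet analysis.  A trailing partial bin is dropped.
#'
#' @param x numeric vector sampled at interval `dt` seconds.
#' @param dt sampling interval, seconds.
#' @param bin_seconds bin width, an integer multiple of `dt`.
#' @return Numeric vector of bin means.
#' @export
bin_mean <- function(x, dt, bin_seconds) {
  k <- bin_seconds / dt
  if (abs(k - round(k)) > 1e-9)
    stop("bin_seconds must be an integer multiple of dt")
  k <- round(k)
  n_bins <- length(x) %/% k
  if (n_bins < 1L) stop("series shorter than one bin")
  .colMeans(x[seq_len(n_bins * k)], k, n_bins)
}
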