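#' Construct a daily count series
#'
#' @param dates Strictly increasing, contiguous calendar dates.
#' @param counts Non-negative integer counts, one per date.
#' @param denoised Optional non-negative reals on the count scale.
#' @return Data frame of class `tweet_series` with columns `date`, `count`
#'   and optionally `denoised`.
#' @export
tweet_series <- function(dates, counts, denoised = NULL) {
  dates <- as.Date(dates)
  if (anyNA(dates)) stop("tweet series: dates must be valid", call. = FALSE)
  if (length(dates) != length(counts))
    stop("tweet series: dates and counts differ in length", call. = FALSE)
  if (length(dates) > 1L && !all(diff(dates) == 1))
    stop("tweet series: dates must be contiguous and strictly increasing by one day",
         call. = FALSE)
  if (any(counts < 0) || anyNA(counts))
    stop("tweet series: counts must be non-negative and non-missing", call. = FALSE)
  x <- data.frame(date = dates, count = as.numeric(counts))
  if (!is.null(denoised)) {
    if (length(denoised) != length(dates) || any(denoised < 0, na.rm = TRUE))
      stop("tweet series: denoised must be non-negative, one value per date",
           call. = FALSE)
    x$denoised <- as.numeric(denoised)
  }
  class(x) <- c("tweet_series", "data.frame")
  x
}

# The working values of a series: denoised if present, raw counts otherwise.
series_values <- function(series) {
  if (is.numeric(series)) return(as.numeric(series))
  stopifnot(inherits(series, "tweet_series"))
  if (!is.null(series$denoised)) series$denoised else series$count
}

#' Detrend a count series by a centered moving median
#'
#' External noise in daily post counts (platform growth, outages) is reduced
#' by dividing each count by the centered moving median over `window_days`
#' days and rescaling by the global median, so the output stays on the count
#' scale. Windows are truncated at the series edges; `window_days = 0`
#' disables denoising (output equals input). Any externally denoised column
#' supplied via [tweet_series()] is equally accepted downstream.
#'
#' @param series A [tweet_series()] (or numeric vector).
#' @param window_days Odd window width >= 1, or 0 for passthrough.
#' @return The series with a `denoised` column added.
#' @export
denoise <- function(series, window_days) {
  x <- if (is.numeric(series)) as.numeric(series) else series$count
  if (!is.numeric(window_days) || length(window_days) != 1L || window_days < 0 ||
      (window_days > 0 && window_days %% 2 == 0))
    stop("window_days must be 0 (passthrough) or an odd integer >= 1", call. = FALSE)
  if (window_days == 0) {
    den <- x
  } else {
    if (all(x == 0)) stop("cannot denoise an all-zero series (no baseline)", call. = FALSE)
    n <- length(x)
    h <- (window_days - 1) / 2
    movmed <- vapply(seq_len(n), function(i)
      stats::median(x[max(1L, i - h):min(n, i + h)]), numeric(1))
    den <- x / movmed * stats::median(x)
    den[!is.finite(den)] <- 0  # flat-zero windows inside a non-zero series
  }
  if (is.numeric(series)) return(den)
  tweet_series(series$date, series$count, denoised = den)
}

#' Previous-day ratio of a series
#'
#' `ratio(d) = x(d) / x(d - 1)`; undefined (NA) on day one and wherever the
#' previous day's value is zero. Operates on the denoised values when
#' present.
#'
#' @param series A [tweet_series()] or numeric vector.
#' @return Numeric vector of ratios with NA where undefined.
#' @export
previous_day_ratio <- function(series) {
  x <- series_values(series)
  if (length(x) < 2L) stop("need at least 2 days for previous-day ratios", call. = FALSE)
  prev <- c(NA_real_, x[-length(x)])
  r <- x / prev
  r[!is.na(prev) & prev == 0] <- NA_real_
  r
}

#' Previous-day difference of a series
#'
#' `x(d) - x(d - 1)`, undefined on day one.
#'
#' @inheritParams previous_day_ratio
#' @return Numeric vector of differences with NA on day one.
#' @export
previous_day_difference <- function(series) {
  x <- series_values(series)
  c(NA_real_, diff(x))
}

#' Nearest-rank percentile
#'
#' The smallest observed value r such that at least `p` percent of the
#' observations are at or below r (rank `ceiling(p/100 * n)` of the sorted
#' values). Deterministic and tie-safe; used for both surge thresholding and
#' the distribution summaries.
#'
#' @param x Numeric; NAs dropped.
#' @param p Percentile in (0, 100].
#' @return The nearest-rank percentile value.
#' @export
nearest_rank <- function(x, p) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n == 0L) stop("no defined values", call. = FALSE)
  if (p <= 0 || p > 100) stop("percentile must be in (0, 100]", call. = FALSE)
  # small guard against upward float error in p/100 * n for exact ranks
  k <- min(n, max(1L, as.integer(ceiling(p * n / 100 - 1e-9))))
  x[k]
}

#' Classify surge (exposed) days by percentile thresholding
#'
#' A day is an exposed day when its previous-day ratio is at or above the
#' configured percentile (nearest-rank) of all defined ratios; days with an
#' undefined ratio (day one, zero previous-day count) have undefined
#' exposure and are excluded from the threshold computation.
#'
#' @param ratios Numeric previous-day ratios (NA where undefined).
#' @param percentile Threshold percentile, default 95.
#' @param dates Optional Date vector parallel to `ratios`; required for
#'   date-keyed merging downstream.
#' @return Data frame of class `exposure_calendar` with columns `date` (if
#'   given), `ratio`, `exposed`, and attributes `threshold` and `percentile`.
#' @examples
#' cal <- classify_surge(c(NA, runif(99) + 1), dates = as.Date("2011-01-01") + 0:99)
#' attr(cal, "threshold")
#' @export
classify_surge <- function(ratios, percentile = 95, dates = NULL) {
  if (!is.numeric(percentile) || percentile <= 0 || percentile >= 100)
    stop("percentile must be strictly between 0 and 100", call. = FALSE)
  defined <- !is.na(ratios)
  if (sum(defined) < 20L)
    stop("need at least 20 defined ratios to set a percentile threshold (got ",
         sum(defined), ")", call. = FALSE)
  threshold <- nearest_rank(ratios, percentile)
  exposed <- ifelse(defined, ratios >= threshold, NA)
  cal <- data.frame(ratio = as.numeric(ratios), exposed = exposed)
  if (!is.null(dates)) {
    dates <- as.Date(dates)
    stopifnot(length(dates) == length(ratios))
    cal <- cbind(date = dates, cal)
  }
  structure(cal, threshold = threshold, percentile = percentile,
            class = c("exposure_calendar", "data.frame"))
}

#' @export
print.exposure_calendar <- function(x, ...) {
  cat("Exposure calendar: ", nrow(x), " days, ",
      sum(x$exposed, na.rm = TRUE), " surge days (ratio >= ",
      format(attr(x, "threshold"), digits = 4), ", the ",
      attr(x, "percentile"), "th percentile); ",
      sum(is.na(x$exposed)), " undefined\n", sep = "")
  invisible(x)
}

#' Build an exposure calendar from a raw count series
#'
#' Convenience wrapper: denoise, take previous-day ratios, threshold.
#'
#' @param series A [tweet_series()].
#' @param percentile Surge threshold percentile.
#' @param denoise_window Moving-median window ([denoise()]); 0 to skip.
#' @return An `exposure_calendar` (see [classify_surge()]).
#' @export
build_exposure_calendar <- function(series, percentile = 95, denoise_window = 0) {
  stopifnot(inherits(series, "tweet_series"))
  series <- denoise(series, denoise_window)
  classify_surge(previous_day_ratio(series), percentile, dates = series$date)
}

# Exposure status at given dates: NA when the date is outside the calendar
# or its exposure is undefined.
calendar_exposure <- function(calendar, dates) {
  stopifnot(inherits(calendar, "exposure_calendar"), !is.null(calendar$date))
  calendar$exposed[match(as.integer(as.Date(dates)), as.integer(calendar$date))]
}

#' Distribution summary of a series and its day-to-day changes
#'
#' Minimum, 5th/25th/50th/95th nearest-rank percentiles and maximum of the
#' daily counts, the previous-day differences, and the previous-day ratios
#' (defined values only).
#'
#' @param series A [tweet_series()].
#' @param ratios,diffs Optional precomputed sequences; derived from the
#'   series when omitted.
#' @return Data frame with one row per sequence and one column per statistic.
#' @export
summarize_series <- function(series, ratios = NULL, diffs = NULL) {
  vals <- series_values(series)
  if (is.null(ratios)) ratios <- previous_day_ratio(series)
  if (is.null(diffs)) diffs <- previous_day_difference(series)
  one <- function(x) {
    x <- x[!is.na(x)]
    c(min = min(x), p5 = nearest_rank(x, 5), p25 = nearest_rank(x, 25),
      p50 = nearest_rank(x, 50), p95 = nearest_rank(x, 95), max = max(x))
  }
  out <- as.data.frame(rbind(tweets = one(vals),
                             previous_day_difference = one(diffs),
                             previous_day_ratio = one(ratios)))
  cbind(sequence = rownames(out), out, row.names = NULL)
}
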