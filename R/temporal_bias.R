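#' Daily observation-count series
#'
#' Tabulates records into a zero-filled series of consecutive calendar dates
#' over `span`. Undated records and records outside the span are dropped and
#' counted in the `"series_log"` attribute. Because records with no date are
#' frequently defaulted to January 1st upstream, `drop_jan1 = TRUE` (the
#' default) masks every January 1st as missing (`NA`) so the artifact cannot
#' leak into trend, seasonality or holiday estimates.
#'
#' @param records Canonical occurrence data.frame.
#' @param span Length-2 `Date` (or coercible) vector, default 2012-01-01 to
#'   2022-12-31.
#' @param drop_jan1 Mask January 1st counts as missing.
#' @return Data.frame with `date` and `count` (NA where masked), class
#'   `daily_count_series`.
#' @export
daily_counts <- function(records, span = c("2012-01-01", "2022-12-31"),
                         drop_jan1 = TRUE) {
  span <- as.Date(span)
  stopifnot(length(span) == 2, span[2] >= span[1])
  dates <- records$event_date
  undated <- sum(is.na(dates))
  dates <- dates[!is.na(dates)]
  outside <- sum(dates < span[1] | dates > span[2])
  dates <- dates[dates >= span[1] & dates <= span[2]]
  all_days <- seq(span[1], span[2], by = "day")
  cnt <- as.integer(table(factor(as.character(dates),
                                 levels = as.character(all_days))))
  out <- data.frame(date = all_days, count = cnt)
  if (drop_jan1) {
    out$count[format(out$date, "%m-%d") == "01-01"] <- NA_integer_
  }
  attr(out, "series_log") <- list(undated = undated, outside_span = outside)
  class(out) <- c("daily_count_series", "data.frame")
  out
}

#' Gregorian date of Easter Sunday
#'
#' Anonymous Gregorian computus (Meeus/Jones/Butcher algorithm), valid for
#' years 1583-4099. Anchors the movable holidays: Good Friday is Easter
#' minus 2 days and Corpus Christi Easter plus 60 days.
#'
#' @param year Integer vector of years.
#' @return `Date` vector of Easter Sundays.
#' @export
#' @examples
#' gregorian_easter(2024) # "2024-03-31"
gregorian_easter <- function(year) {
  stopifnot(all(year >= 1583 & year <= 4099))
  a <- year %% 19
  b <- year %/% 100
  c <- year %% 100
  d <- b %/% 4
  e <- b %% 4
  f <- (b + 8) %/% 25
  g <- (b - f + 1) %/% 3
  h <- (19 * a + b - d - g + 15) %% 30
  i <- c %/% 4
  k <- c %% 4
  l <- (32 + 2 * e + 2 * i - h - k) %% 7
  m <- (a + 11 * h + 22 * l) %/% 451
  month <- (h + l - 7 * m + 114) %/% 31
  day <- ((h + l - 7 * m + 114) %% 31) + 1
  as.Date(sprintf("%04d-%02d-%02d", year, month, day))
}

FIXED_HOLIDAYS <- data.frame(
  name = c("Epiphany", "Freedom Day", "Labour Day", "Portugal Day",
           "Asuncion", "Republic Day", "Hispanity Day", "All Saints",
           "Restoration Day", "Constitution Day", "Inmaculada", "Christmas"),
  month = c(1L, 4L, 5L, 6L, 8L, 10L, 10L, 11L, 12L, 12L, 12L, 12L),
  day = c(6L, 25L, 1L, 10L, 15L, 5L, 12L, 1L, 1L, 6L, 8L, 25L),
  stringsAsFactors = FALSE
)

#' National holiday calendar (Spain and Portugal)
#'
#' The twelve fixed official national holidays of the two countries plus the
#' movable feasts Good Friday (Easter - 2 days) and Corpus Christi
#' (Easter + 60 days). January 1st is never included: in aggregated
#' occurrence data it is a missing-date artifact, not a usable holiday
#' signal. Holidays falling on a Saturday or Sunday are flagged
#' (`weekend = TRUE`) and excluded from holiday-effect estimation so the
#' holiday signal is not confounded with the weekend effect. Regional and
#' substituted holidays are ignored.
#'
#' @param years Integer vector of years.
#' @return Data.frame with `date`, `name`, `year`, `weekday` (ISO, Mon=1)
#'   and `weekend`.
#' @export
holiday_calendar <- function(years) {
  years <- sort(unique(as.integer(years)))
  fixed <- do.call(rbind, lapply(years, function(y) {
    data.frame(date = as.Date(sprintf("%04d-%02d-%02d", y,
                                      FIXED_HOLIDAYS$month,
                                      FIXED_HOLIDAYS$day)),
               name = FIXED_HOLIDAYS$name, stringsAsFactors = FALSE)
  }))
  easter <- gregorian_easter(years)
  movable <- data.frame(
    date = c(easter - 2, easter + 60),
    name = rep(c("Good Friday", "Corpus Christi"), each = length(years)),
    stringsAsFactors = FALSE
  )
  cal <- rbind(fixed, movable)
  cal <- cal[order(cal$date), ]
  cal$year <- as.integer(format(cal$date, "%Y"))
  cal$weekday <- iso_weekday(cal$date)
  cal$weekend <- cal$weekday >= 6
  rownames(cal) <- NULL
  cal
}

# ISO-8601 weekday, Monday = 1 .. Sunday = 7.
iso_weekday <- function(date) {
  wd <- as.POSIXlt(date)$wday
  ifelse(wd == 0, 7L, wd)
}

WEEKDAY_NAMES <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")

#' Additive weekly decomposition of a daily count series
#'
#' Classical additive decomposition: the trend is a centered, missing-aware
#' 7-day moving average; the weekly component is the mean detrended value
#' per ISO weekday, recentred so the seven values sum to zero; the residual
#' is the remainder, so `count = trend + weekly[weekday] + residual` holds
#' exactly on every unmasked date where the trend is defined. Masked (NA)
#' dates are simply skipped by every average, and the trend (hence residual)
#' is undefined on the first and last three days, where no centered window
#' exists.
#'
#' @param series A [daily_counts()] series (>= 8 weeks long).
#' @param min_window Minimum non-missing days in the 7-day window for the
#'   trend to be defined (default 4).
#' @return A `seasonal_decomposition` list: `table` (date, count, weekday,
#'   trend, weekly, residual), and `weekly` (named 7-vector, Mon..Sun).
#' @export
decompose_weekly <- function(series, min_window = 4) {
  stopifnot(all(c("date", "count") %in% names(series)))
  n <- nrow(series)
  if (n < 56) stop("series must span at least 8 weeks")
  y <- as.numeric(series$count)
  if (all(is.na(y) | y == 0)) warning("all-zero series: components are zero")
  # centered missing-aware MA-7
  obs <- ifelse(is.na(y), 0, y)
  avail <- as.numeric(!is.na(y))
  ksum <- stats::filter(obs, rep(1, 7), sides = 2)
  kcnt <- stats::filter(avail, rep(1, 7), sides = 2)
  # trend undefined on the first/last 3 days (no centered window) and where
  # too few unmasked days fall in the window
  trend <- ifelse(!is.na(kcnt) & kcnt >= min_window, ksum / kcnt, NA_real_)
  wd <- iso_weekday(series$date)
  det <- y - trend
  weekly_raw <- vapply(1:7, function(d) mean(det[wd == d], na.rm = TRUE),
                       numeric(1))
  weekly <- weekly_raw - mean(weekly_raw)
  names(weekly) <- WEEKDAY_NAMES
  resid <- y - trend - weekly[wd]
  out <- list(table = data.frame(date = series$date, count = y, weekday = wd,
                                 trend = as.numeric(trend),
                                 weekly = unname(weekly[wd]),
                                 residual = as.numeric(resid)),
              weekly = weekly)
  class(out) <- "seasonal_decomposition"
  out
}

#' @export
print.seasonal_decomposition <- function(x, ...) {
  cat("Weekly decomposition over", nrow(x$table), "days\n")
  print(round(x$weekly, 3))
  invisible(x)
}

#' Per-holiday effects on daily record counts
#'
#' The effect of a holiday is the mean decomposition residual over its dates
#' within the series span, using only years where the holiday falls on a
#' weekday (weekend occurrences are excluded to avoid confounding the
#' holiday and weekend effects). Negative effects mean fewer records were
#' collected than trend plus weekly seasonality predicts.
#'
#' @param decomposition A [decompose_weekly()] result.
#' @param calendar A [holiday_calendar()] (restricted to the span
#'   automatically).
#' @return Data.frame with `name`, `effect` (mean residual), `n_years`;
#'   plus the overall mean as attribute `"overall"`.
#' @export
holiday_effects <- function(decomposition, calendar) {
  tab <- decomposition$table
  cal <- calendar[!calendar$weekend &
                    calendar$date >= min(tab$date) &
                    calendar$date <= max(tab$date), , drop = FALSE]
  m <- match(cal$date, tab$date)
  cal$residual <- tab$residual[m]
  cal <- cal[!is.na(cal$residual), , drop = FALSE]
  if (nrow(cal) == 0) {
    warning("no usable holiday dates in span")
    out <- data.frame(name = character(), effect = numeric(),
                      n_years = integer())
    attr(out, "overall") <- NA_real_
    return(out)
  }
  eff <- aggregate(residual ~ name, data = cal, FUN = mean)
  nyr <- aggregate(residual ~ name, data = cal, FUN = length)
  out <- data.frame(name = eff$name, effect = eff$residual,
                    n_years = nyr$residual, stringsAsFactors = FALSE)
  out <- out[order(out$effect), ]
  rownames(out) <- NULL
  attr(out, "overall") <- mean(cal$residual)
  out
}
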