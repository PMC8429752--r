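#' Thermal configuration
#'
#' Bundles the temperature thresholds used throughout the package: the cold
#' threshold below which daily chill deficits accumulate (low-temperature
#' degree-days, LTDD), and the developmental band over which effective
#' temperature degree-days (ETDD) accumulate.
#'
#' @param cold_threshold Cold threshold in degrees Celsius. Daily mean
#'   temperatures below this value contribute their deficit to LTDD.
#'   Default 11.0.
#' @param dev_lower,dev_upper Lower and upper bounds (degrees Celsius) of the
#'   developmental band used for ETDD. Defaults 7.4 and 33.0.
#' @return An object of class `thermal_config`.
#' @examples
#' cfg <- thermal_config()
#' cfg$cold_threshold
#' @export
thermal_config <- function(cold_threshold = 11.0, dev_lower = 7.4,
                           dev_upper = 33.0) {
  stopifnot(is.finite(cold_threshold), is.finite(dev_lower),
            is.finite(dev_upper))
  if (dev_lower >= dev_upper)
    stop("dev_lower must be strictly below dev_upper", call. = FALSE)
  structure(list(cold_threshold = cold_threshold,
                 dev_lower = dev_lower,
                 dev_upper = dev_upper),
            class = "thermal_config")
}

#' Daily temperature series for one site
#'
#' Constructs a validated series of daily mean air temperatures for a site.
#' Dates must be strictly increasing with a daily step (no duplicates);
#' temperatures must be finite.
#'
#' @param site_id Character label for the site.
#' @param dates `Date` vector (or coercible), strictly increasing, daily step.
#' @param temps Numeric vector of daily mean temperatures (degrees C), same
#'   length as `dates`.
#' @param latitude,longitude Optional site coordinates in decimal degrees.
#' @return An object of class `temp_series`: a list with elements `site_id`,
#'   `latitude`, `longitude`, `dates`, `temps`.
#' @export
temperature_series <- function(site_id, dates, temps,
                               latitude = NA_real_, longitude = NA_real_) {
  dates <- as.Date(dates)
  temps <- as.numeric(temps)
  if (length(dates) != length(temps))
    stop("dates and temps must have equal length", call. = FALSE)
  if (length(dates) == 0L)
    stop("empty series", call. = FALSE)
  if (anyNA(dates)) stop("dates contain NA", call. = FALSE)
  if (any(!is.finite(temps)))
    stop("temps must be finite", call. = FALSE)
  d <- diff(as.integer(dates))
  if (length(d) && any(d <= 0L))
    stop("dates must be strictly increasing", call. = FALSE)
  if (!is.na(latitude) && abs(latitude) > 90)
    stop("latitude out of range", call. = FALSE)
  structure(list(site_id = as.character(site_id),
                 latitude = as.numeric(latitude),
                 longitude = as.numeric(longitude),
                 dates = dates, temps = temps),
            class = "temp_series")
}

#' @export
print.temp_series <- function(x, ...) {
  cat(sprintf("<temp_series> site %s: %d days, %s .. %s, %.1f to %.1f degC\n",
              x$site_id, length(x$dates), format(min(x$dates)),
              format(max(x$dates)), min(x$temps), max(x$temps)))
  invisible(x)
}

#' Read / write daily temperature series
#'
#' CSV with columns `site_id`, `date` (ISO-8601), `tmean_c` and optional
#' `lat`, `lon`.
#'
#' @param path File path.
#' @return For `read_temperature_series`, a list of `temp_series`, one per
#'   site in the file.
#' @export
read_temperature_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("site_id", "date", "tmean_c")
  if (!all(req %in% names(df)))
    stop("CSV must have columns site_id, date, tmean_c", call. = FALSE)
  lapply(split(df, df$site_id), function(s) {
    s <- s[order(as.Date(s$date)), ]
    temperature_series(
      site_id = s$site_id[1], dates = s$date, temps = s$tmean_c,
      latitude = if ("lat" %in% names(s)) s$lat[1] else NA_real_,
      longitude = if ("lon" %in% names(s)) s$lon[1] else NA_real_)
  })
}

#' @rdname read_temperature_series
#' @param series A `temp_series` or list of them.
#' @export
write_temperature_series <- function(series, path) {
  if (inherits(series, "temp_series")) series <- list(series)
  df <- do.call(rbind, lapply(series, function(s)
    data.frame(site_id = s$site_id, date = format(s$dates),
               tmean_c = s$temps, lat = s$latitude, lon = s$longitude)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Daily cold deficit below the threshold
#'
#' The per-day contribution to LTDD: `max(0, cold_threshold - temp)`.
#' Days at or above the threshold contribute nothing.
#'
#' @param temp Numeric vector of daily mean temperatures (degrees C).
#' @param config A [thermal_config()].
#' @return Numeric vector of deficits in degC-day, same length as `temp`.
#' @examples
#' daily_cold_deficit(c(11, 15, 1))  # 0, 0, 10
#' @export
daily_cold_deficit <- function(temp, config = thermal_config()) {
  if (any(!is.finite(temp)))
    stop("temp must be finite", call. = FALSE)
  pmax(0, config$cold_threshold - temp)
}

#' Hemisphere-aware annual accumulation window
#'
#' Northern-hemisphere sites (latitude >= 0, the equator assigned north for
#' determinism) accumulate cold over the cross-calendar winter: July 1 of the
#' label year through June 30 of the following year. Southern-hemisphere
#' sites use the calendar year, whose middle is their winter.
#'
#' @param latitude Site latitude in decimal degrees.
#' @param year Integer label year.
#' @return An object of class `annual_window`: list with `label_year`,
#'   `hemisphere`, `start_date`, `end_date`.
#' @examples
#' annual_window_for(40, 2000)   # 2000-07-01 .. 2001-06-30
#' annual_window_for(-30, 2000)  # 2000-01-01 .. 2000-12-31
#' @export
annual_window_for <- function(latitude, year) {
  if (!is.finite(latitude) || abs(latitude) > 90)
    stop("latitude must be in [-90, 90]", call. = FALSE)
  year <- as.integer(year)
  if (latitude >= 0) {
    w <- list(label_year = year, hemisphere = "north",
              start_date = as.Date(sprintf("%d-07-01", year)),
              end_date = as.Date(sprintf("%d-06-30", year + 1L)))
  } else {
    w <- list(label_year = year, hemisphere = "south",
              start_date = as.Date(sprintf("%d-01-01", year)),
              end_date = as.Date(sprintf("%d-12-31", year)))
  }
  structure(w, class = "annual_window")
}

# Extract (and, within the allowed gap fraction, linearly interpolate) the
# daily temperatures of a series over [start, end]. Missing interior days are
# interpolated from neighbours; missing edges take the nearest observed value.
.window_temps <- function(series, start, end, max_gap_frac = 0.02) {
  start <- as.Date(start); end <- as.Date(end)
  if (end < start) stop("empty date range", call. = FALSE)
  days <- seq(start, end, by = "day")
  idx <- match(days, series$dates)
  n_missing <- sum(is.na(idx))
  if (n_missing > max_gap_frac * length(days))
    stop(sprintf(
      "coverage error: %d of %d days missing in %s..%s for site %s",
      n_missing, length(days), format(start), format(end), series$site_id),
      call. = FALSE)
  temps <- series$temps[idx]
  if (n_missing > 0L) {
    known <- !is.na(temps)
    temps <- stats::approx(as.numeric(days[known]), temps[known],
                           xout = as.numeric(days), rule = 2)$y
  }
  temps
}

#' Low-temperature degree-days over a window
#'
#' Sums the daily cold deficits (`max(0, threshold - temp)`) of a series over
#' an annual window or explicit date range. The sum runs over the actual
#' calendar days of the window (366 in leap years). Up to `max_gap_frac` of
#' the window's days may be missing from the series; they are filled by
#' linear interpolation between neighbouring days. More missing days raise a
#' coverage error.
#'
#' @param series A [temperature_series()].
#' @param window An `annual_window` (see [annual_window_for()]), or `NULL`
#'   when `start`/`end` are given.
#' @param start,end Explicit date range (used when `window` is `NULL`).
#' @param config A [thermal_config()].
#' @param max_gap_frac Maximum tolerated fraction of missing days.
#' @return LTDD in degC-day (scalar, >= 0).
#' @examples
#' s <- temperature_series("x", as.Date("2000-01-01") + 0:9, rep(1, 10))
#' ltdd(s, start = "2000-01-01", end = "2000-01-10")  # 100
#' @export
ltdd <- function(series, window = NULL, start = NULL, end = NULL,
                 config = thermal_config(), max_gap_frac = 0.02) {
  if (!is.null(window)) {
    start <- window$start_date; end <- window$end_date
  }
  if (is.null(start) || is.null(end))
    stop("supply either window or start and end", call. = FALSE)
  temps <- .window_temps(series, start, end, max_gap_frac)
  sum(daily_cold_deficit(temps, config))
}

#' Effective temperature degree-days over a calendar year
#'
#' Accumulates daily degrees within the developmental band: each day
#' contributes `max(0, min(temp, dev_upper) - dev_lower)`. The window is the
#' calendar year at all latitudes (a growing-season covariate, with no
#' hemisphere split).
#'
#' @inheritParams ltdd
#' @param year Calendar year.
#' @return ETDD in degC-day (scalar, >= 0).
#' @export
etdd <- function(series, year, config = thermal_config(),
                 max_gap_frac = 0.02) {
  temps <- .window_temps(series, sprintf("%d-01-01", year),
                         sprintf("%d-12-31", year), max_gap_frac)
  sum(pmax(0, pmin(temps, config$dev_upper) - config$dev_lower))
}

#' Lowest daily mean temperature in a range
#'
#' @inheritParams ltdd
#' @return Minimum daily mean temperature (degrees C) over the range.
#' @export
min_dt_mean <- function(series, start, end, max_gap_frac = 0.02) {
  min(.window_temps(series, start, end, max_gap_frac))
}

#' Mean daily temperature and exposure duration of a range
#'
#' Averages the daily mean temperatures over all days of the exposure window
#' and pairs the mean with the number of days; the duration carries the
#' exposure-time information as a separate covariate.
#'
#' @inheritParams ltdd
#' @return List with `mean` (degrees C) and `days` (integer count).
#' @export
dt_mean_exposure <- function(series, start, end, max_gap_frac = 0.02) {
  temps <- .window_temps(series, start, end, max_gap_frac)
  list(mean = mean(temps), days = length(temps))
}

#' Multi-year mean annual LTDD
#'
#' Arithmetic mean of annual LTDD over the `n_years` hemisphere-aware windows
#' with label years `end_year - n_years + 1` through `end_year`.
#'
#' @inheritParams ltdd
#' @param end_year Label year of the last window.
#' @param n_years Number of annual windows to average (default 5).
#' @param latitude Site latitude; defaults to the series' latitude.
#' @return Mean annual LTDD in degC-day.
#' @export
multi_year_mean_ltdd <- function(series, end_year, n_years = 5,
                                 config = thermal_config(),
                                 latitude = series$latitude,
                                 max_gap_frac = 0.02) {
  stopifnot(n_years >= 1)
  yrs <- seq(end_year - n_years + 1L, end_year)
  vals <- vapply(yrs, function(y)
    ltdd(series, annual_window_for(latitude, y), config = config,
         max_gap_frac = max_gap_frac), numeric(1))
  mean(vals)
}
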