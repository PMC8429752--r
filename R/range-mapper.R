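#' Gridded daily mean temperature cube
#'
#' A regular latitude x longitude grid of daily mean temperatures, the
#' substrate for projecting the survival model globally.
#'
#' @param lats,lons Numeric vectors of cell-centre coordinates (degrees).
#' @param dates `Date` vector of the daily time axis.
#' @param tmean Numeric array of dimension `c(length(lats), length(lons),
#'   length(dates))`, degrees Celsius.
#' @param scenario Optional character tag (e.g. a warming scenario label).
#' @return Object of class `climate_grid`.
#' @export
climate_grid <- function(lats, lons, dates, tmean, scenario = "historical") {
  dates <- as.Date(dates)
  stopifnot(is.array(tmean),
            identical(dim(tmean),
                      c(length(lats), length(lons), length(dates))))
  if (any(!is.finite(tmean))) stop("tmean must be finite", call. = FALSE)
  if (length(dates) > 1 && any(diff(as.integer(dates)) != 1L))
    stop("dates must be consecutive days", call. = FALSE)
  structure(list(lats = as.numeric(lats), lons = as.numeric(lons),
                 dates = dates, tmean = tmean, scenario = scenario),
            class = "climate_grid")
}

#' @export
print.climate_grid <- function(x, ...) {
  cat(sprintf("<climate_grid> %d x %d cells, %d days (%s .. %s), scenario %s\n",
              length(x$lats), length(x$lons), length(x$dates),
              format(min(x$dates)), format(max(x$dates)), x$scenario))
  invisible(x)
}

# temp_series view of one grid cell
.cell_series <- function(grid, i, j) {
  temperature_series(sprintf("cell_%g_%g", grid$lats[i], grid$lons[j]),
                     grid$dates, grid$tmean[i, j, ],
                     latitude = grid$lats[i], longitude = grid$lons[j])
}

#' Per-cell annual LTDD on a climate grid
#'
#' Applies the hemisphere-aware annual window of each cell's latitude and
#' accumulates the daily cold deficits below the threshold.
#'
#' @param grid A [climate_grid()].
#' @param year Label year of the annual window.
#' @param config A [thermal_config()].
#' @return Numeric matrix `[lat, lon]` of LTDD (degC-day).
#' @export
annual_ltdd_grid <- function(grid, year, config = thermal_config()) {
  out <- matrix(NA_real_, length(grid$lats), length(grid$lons))
  for (i in seq_along(grid$lats)) {
    w <- annual_window_for(grid$lats[i], year)
    idx <- which(grid$dates >= w$start_date & grid$dates <= w$end_date)
    n_days <- as.integer(w$end_date - w$start_date) + 1L
    if (length(idx) != n_days)
      stop(sprintf("coverage error: window %d..%d not covered at lat %g",
                   year, year, grid$lats[i]), call. = FALSE)
    block <- grid$tmean[i, , idx, drop = FALSE]
    def <- pmax(config$cold_threshold - block, 0)  # keeps array dims
    out[i, ] <- apply(def, 2, sum)
  }
  out
}

#' Per-cell annual ETDD on a climate grid
#'
#' Calendar-year accumulation within the developmental band, at every
#' latitude (no hemisphere split: a growing-season covariate).
#'
#' @inheritParams annual_ltdd_grid
#' @return Numeric matrix `[lat, lon]` of ETDD (degC-day).
#' @export
annual_etdd_grid <- function(grid, year, config = thermal_config()) {
  idx <- which(grid$dates >= as.Date(sprintf("%d-01-01", year)) &
               grid$dates <= as.Date(sprintf("%d-12-31", year)))
  n_days <- as.integer(as.Date(sprintf("%d-12-31", year)) -
                       as.Date(sprintf("%d-01-01", year))) + 1L
  if (length(idx) != n_days)
    stop(sprintf("coverage error: calendar year %d not covered", year),
         call. = FALSE)
  block <- grid$tmean[, , idx, drop = FALSE]
  apply(pmax(pmin(block, config$dev_upper) - config$dev_lower, 0),
        c(1, 2), sum)
}

#' Multi-year mean survival grid
#'
#' Predicts yearly winter survival per cell from the annual LTDD of each of
#' `years`, then averages. The model must use the LTDD predictor.
#'
#' @param grid A [climate_grid()].
#' @param model An `ows_fit` with predictor `"LTDD"`.
#' @param years Integer vector of window label years (e.g. the five years of
#'   a baseline period).
#' @param config A [thermal_config()].
#' @return Numeric matrix `[lat, lon]` of mean survival in [0, 1].
#' @export
survival_grid <- function(grid, model, years, config = thermal_config()) {
  if (model$spec$predictor != "LTDD")
    stop("survival_grid requires an LTDD-driven model", call. = FALSE)
  preds <- lapply(years, function(y) {
    lt <- annual_ltdd_grid(grid, y, config)
    matrix(predict(model, as.numeric(lt)), nrow(lt), ncol(lt))
  })
  Reduce(`+`, preds) / length(preds)
}

#' Classify overwintering status per grid cell
#'
#' Cells are labelled by modelled mean winter survival: `permanent`
#' (survival >= 0.05), `marginal` (0.01 <= survival < 0.05), `transient`
#' (survival < 0.01). Cells whose host-plant presence probability is below
#' 0.3 are `masked`, overriding the climate class.
#'
#' @param survival Numeric matrix of per-cell survival in [0, 1].
#' @param host_mask Numeric matrix of host presence probabilities in [0, 1],
#'   same dimensions, or `NULL` for no mask.
#' @param lats,lons Cell-centre coordinates (for area accounting).
#' @param permanent_min,marginal_min Survival thresholds (defaults 0.05,
#'   0.01).
#' @param host_min Host presence threshold (default 0.3).
#' @return Object of class `overwinter_map`: list with `lats`, `lons`,
#'   `survival`, `owclass` (character matrix) and the thresholds used.
#' @export
classify_overwintering <- function(survival, host_mask = NULL, lats, lons,
                                   permanent_min = 0.05, marginal_min = 0.01,
                                   host_min = 0.3) {
  survival <- as.matrix(survival)
  if (!is.null(host_mask)) {
    host_mask <- as.matrix(host_mask)
    if (!identical(dim(host_mask), dim(survival)))
      stop("host mask geometry does not match survival grid", call. = FALSE)
  }
  if (!identical(dim(survival), c(length(lats), length(lons))))
    stop("lats/lons do not match survival grid", call. = FALSE)
  cls <- matrix("transient", nrow(survival), ncol(survival))
  cls[survival >= marginal_min] <- "marginal"
  cls[survival >= permanent_min] <- "permanent"
  if (!is.null(host_mask)) cls[host_mask < host_min] <- "masked"
  structure(list(lats = lats, lons = lons, survival = survival,
                 owclass = cls, permanent_min = permanent_min,
                 marginal_min = marginal_min, host_min = host_min),
            class = "overwinter_map")
}

#' @export
print.overwinter_map <- function(x, ...) {
  tab <- table(factor(x$owclass,
                      levels = c("permanent", "marginal", "transient",
                                 "masked")))
  cat("<overwinter_map>", length(x$lats), "x", length(x$lons), "cells:\n")
  print(tab)
  invisible(x)
}

#' Area of a 1-degree grid cell
#'
#' Spherical cos-latitude weighting at the cell centre:
#' `(2*pi*R/360)^2 * cos(lat)` with mean Earth radius R = 6371 km, i.e.
#' `111.195^2 * cos(lat)` km^2.
#'
#' @param latitude Latitude in decimal degrees (vectorized).
#' @return Cell area in km^2.
#' @examples
#' cell_area_km2(0)    # ~12364 km^2
#' cell_area_km2(60)   # half of the equator value
#' @export
cell_area_km2 <- function(latitude) {
  if (any(abs(latitude) > 90)) stop("latitude out of range", call. = FALSE)
  111.195^2 * cos(latitude * pi / 180)
}

#' Count and area of the overwintering range
#'
#' Unmasked cells with survival at or above the cutoff, with cos-latitude
#' weighted area.
#'
#' @param map An `overwinter_map`.
#' @param survival_cutoff Survival threshold (typically 0.05 for permanent
#'   range or 0.01 to include the marginal belt).
#' @return List with `cells` (count) and `area_km2`.
#' @export
overwinter_area <- function(map, survival_cutoff = 0.05) {
  qual <- map$owclass != "masked" & map$survival >= survival_cutoff
  area_by_row <- cell_area_km2(map$lats)
  list(cells = sum(qual),
       area_km2 = sum(area_by_row * rowSums(qual)))
}

#' Range expansion relative to a baseline year
#'
#' Classifies each year's single-year survival grid, computes the
#' overwintering area at the >= 1 % and >= 5 % cutoffs, and differences each
#' year against the baseline. Non-overlapping 5-year block means anchored at
#' the baseline year summarise the series.
#'
#' @param grid A multi-year [climate_grid()].
#' @param model An LTDD-driven `ows_fit`.
#' @param host_mask Host presence matrix or `NULL`.
#' @param years Integer vector of window label years to evaluate.
#' @param baseline_year Baseline label year (must be in `years`).
#' @param config A [thermal_config()].
#' @return List with `yearly` (data frame: year, area at both cutoffs and
#'   deltas vs baseline) and `blocks` (data frame of 5-year block means of
#'   the deltas).
#' @export
expansion_series <- function(grid, model, host_mask, years, baseline_year,
                             config = thermal_config()) {
  if (!baseline_year %in% years)
    stop("baseline year missing from years", call. = FALSE)
  rows <- lapply(years, function(y) {
    sv <- survival_grid(grid, model, y, config)
    m <- classify_overwintering(sv, host_mask, grid$lats, grid$lons)
    data.frame(year = y,
               area_ge5 = overwinter_area(m, 0.05)$area_km2,
               area_ge1 = overwinter_area(m, 0.01)$area_km2,
               cells_ge5 = overwinter_area(m, 0.05)$cells,
               cells_ge1 = overwinter_area(m, 0.01)$cells)
  })
  yearly <- do.call(rbind, rows)
  base <- yearly[yearly$year == baseline_year, ]
  yearly$delta_ge5 <- yearly$area_ge5 - base$area_ge5
  yearly$delta_ge1 <- yearly$area_ge1 - base$area_ge1
  block_id <- (yearly$year - baseline_year) %/% 5L
  blocks <- do.call(rbind, lapply(split(yearly, block_id), function(b)
    data.frame(period = sprintf("%d-%d", min(b$year), max(b$year)),
               delta_ge5 = mean(b$delta_ge5),
               delta_ge1 = mean(b$delta_ge1))))
  rownames(blocks) <- NULL
  list(yearly = yearly, blocks = blocks)
}

#' Uniform warming scenario
#'
#' Shifts every daily temperature of the grid by `delta_t` degrees and tags
#' the scenario in the metadata.
#'
#' @param grid A [climate_grid()].
#' @param delta_t Temperature increment in degrees C.
#' @return A new `climate_grid`.
#' @export
warming_scenario <- function(grid, delta_t) {
  stopifnot(is.finite(delta_t))
  climate_grid(grid$lats, grid$lons, grid$dates, grid$tmean + delta_t,
               scenario = sprintf("%+g degC", delta_t))
}

#' LTDD trend over the marginal overwintering belt
#'
#' Selects the cells classified marginal (survival in [1 %, 5 %), host
#' present) in the baseline year, averages their annual LTDD for each year,
#' and fits an ordinary least-squares linear trend against year. The
#' reported p-value is the regression's overall F-test, equivalent to the
#' slope's two-sided t-test in this single-predictor model.
#'
#' @inheritParams expansion_series
#' @return List with `slope` (degC-day per year), `intercept`, `r2`, `p`,
#'   `n_cells`, and the per-year belt means in `series`.
#' @export
marginal_belt_trend <- function(grid, model, host_mask, years,
                                baseline_year = min(years),
                                config = thermal_config()) {
  sv <- survival_grid(grid, model, baseline_year, config)
  m <- classify_overwintering(sv, host_mask, grid$lats, grid$lons)
  belt <- m$owclass == "marginal"
  if (!any(belt)) stop("empty marginal belt in baseline year", call. = FALSE)
  mean_ltdd <- vapply(years, function(y) {
    lt <- annual_ltdd_grid(grid, y, config)
    mean(lt[belt])
  }, numeric(1))
  lf <- stats::lm(mean_ltdd ~ years)
  sm <- summary(lf)
  p <- if (is.null(sm$fstatistic)) NA_real_ else
    unname(stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                     lower.tail = FALSE))
  list(slope = unname(stats::coef(lf)[2]),
       intercept = unname(stats::coef(lf)[1]),
       r2 = sm$r.squared, p = p, n_cells = sum(belt),
       series = data.frame(year = years, mean_ltdd = mean_ltdd))
}

#' Write an overwinter map as a CSV grid
#'
#' Long-format CSV with one row per cell: `lat`, `lon`, `survival`, `class`
#' and a numeric `class_code` (0 transient, 1 marginal, 2 permanent,
#' 9 masked).
#'
#' @param map An `overwinter_map`.
#' @param path Output path.
#' @export
write_overwinter_map <- function(map, path) {
  codes <- c(transient = 0L, marginal = 1L, permanent = 2L, masked = 9L)
  df <- expand.grid(lat = map$lats, lon = map$lons,
                    KEEP.OUT.ATTRS = FALSE)
  df$survival <- as.vector(map$survival)
  df$class <- as.vector(map$owclass)
  df$class_code <- codes[df$class]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
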