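# Shared fixtures, built in code.

# constant-temperature series of `n` days starting at `start`
const_series <- function(temp, n, start = "2000-01-01", site = "s1",
                         lat = 40) {
  temperature_series(site, as.Date(start) + seq_len(n) - 1, rep(temp, n),
                     latitude = lat)
}

# series from an explicit temperature vector
vec_series <- function(temps, start = "2000-01-01", site = "s1", lat = 40) {
  temperature_series(site, as.Date(start) + seq_along(temps) - 1, temps,
                     latitude = lat)
}

# independent scalar per-day loop oracle for LTDD (no vectorization)
ltdd_loop_oracle <- function(temps, threshold = 11.0) {
  total <- 0
  for (t in temps) if (t < threshold) total <- total + (threshold - t)
  total
}

# independent scalar oracle for ETDD
etdd_loop_oracle <- function(temps, lower = 7.4, upper = 33.0) {
  total <- 0
  for (t in temps) {
    t2 <- if (t > upper) upper else t
    if (t2 > lower) total <- total + (t2 - lower)
  }
  total
}

# an exponential-LTDD ows_fit with known coefficients, no refit needed
known_exp_model <- function(a = 0.9, b = -0.005) {
  structure(list(spec = survival_spec("LTDD", "exponential"),
                 coefficients = c(a = a, b = b), r2 = NA_real_,
                 aic = NA_real_, n_obs = 0L, residual_ss = NA_real_,
                 fitted = NULL, data = NULL, converged = TRUE,
                 vcov = NULL, k = 2L),
            class = "ows_fit")
}

# tiny deterministic climate grid: constant temperature per cell
const_grid <- function(temp, lats = c(-10, 10), lons = c(0, 1),
                       years = 2000:2001) {
  dates <- seq(as.Date(sprintf("%d-01-01", min(years))),
               as.Date(sprintf("%d-06-30", max(years) + 1)), by = "day")
  tm <- array(temp, c(length(lats), length(lons), length(dates)))
  climate_grid(lats, lons, dates, tm)
}

# minimal complete resistance-record data frame
basic_records <- function(rr, n_field = 100, n_sus = 100,
                          lc50_sus = 1, se_f = 0.5, se_s = 0.5) {
  k <- length(rr)
  lc50_f <- lc50_sus * rr
  data.frame(
    pesticide = rep("p1", k), moa_group = rep("m1", k),
    latitude = rep(0, k), longitude = rep(0, k), year = rep(2000L, k),
    lc50_field = lc50_f,
    ci_field_lo = lc50_f - 1.96 * se_f, ci_field_hi = lc50_f + 1.96 * se_f,
    n_field = rep(n_field, k),
    lc50_susceptible = rep(lc50_sus, k),
    ci_sus_lo = lc50_sus - 1.96 * se_s, ci_sus_hi = lc50_sus + 1.96 * se_s,
    n_susceptible = rep(n_sus, k),
    rr = rr)
}
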