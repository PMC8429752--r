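#' Ground-truth parameters for the synthetic generators
#'
#' One bundle of known parameter values threaded through every generator so
#' that recovery tests can compare estimates against truth. Defaults mimic
#' the magnitudes of the study system without claiming to be fitted values:
#' winter survival `S = a*exp(b*LTDD)` with `a = 0.9`, `b = -0.005` per
#' degC-day (LTDD spanning roughly 0-1500 degC-day across sites); resistance
#' ratios spanning roughly 0.1-1e4 with overwintering-type log-fold effects
#' of 0 (transient), log(31.6) (marginal) and log(158) (permanent), matching
#' the order of magnitude of the contrasts the meta-analysis is designed to
#' detect.
#'
#' @param a,b Exponential survival parameters (`a` in (0,1], `b` <= 0).
#' @param ow_effect Named log-scale overwintering-type effects.
#' @param pesticide_sd SD of per-pesticide log effects.
#' @param etdd_slope Log-RR change per degC-day of ETDD.
#' @param site_year_sd SD of the site-by-year random intercept (log scale).
#' @param residual_sd Residual SD of log RR.
#' @param v_mean,v_sdlog Mean and log-scale SD of the per-record sampling
#'   variance of logRR encoded into the generated CIs.
#' @param mu Baseline log RR of a transient site.
#' @param grid_trend Warming trend of the synthetic climate grid, degC per
#'   year.
#' @param grid_noise_sd Day-to-day temperature noise SD, degC.
#' @return List of class `truth_params`.
#' @export
truth_params <- function(a = 0.9, b = -0.005,
                         ow_effect = c(transient = 0,
                                       marginal = log(158 / 5),
                                       permanent = log(158)),
                         pesticide_sd = 1.5, etdd_slope = 2e-4,
                         site_year_sd = 0.5, residual_sd = 1.0,
                         v_mean = 0.05, v_sdlog = 0.5, mu = 0.4,
                         grid_trend = 0.03, grid_noise_sd = 1.5) {
  stopifnot(a > 0, a <= 1, b <= 0, site_year_sd >= 0, residual_sd >= 0)
  structure(list(survival = c(a = a, b = b), ow_effect = ow_effect,
                 pesticide_sd = pesticide_sd, etdd_slope = etdd_slope,
                 site_year_sd = site_year_sd, residual_sd = residual_sd,
                 v_mean = v_mean, v_sdlog = v_sdlog, mu = mu,
                 grid_trend = grid_trend, grid_noise_sd = grid_noise_sd),
            class = "truth_params")
}

#' Piecewise-linear laboratory winter temperature regimes
#'
#' Emulates chamber regimes for a latitudinal gradient of sites: each regime
#' is a ~180-day (November-April) sequence built from a linear decline, a
#' horizontal hold at the site's winter minimum, and a linear rise, with the
#' set temperature adjusted every 10 days. Site minima span a cold-to-warm
#' gradient so that accumulated LTDD varies at least five-fold across sites.
#'
#' @param n_sites Number of regimes (default 10).
#' @param seed Integer seed (regimes are deterministic given the seed).
#' @param start_date First day of the regimes (default 2010-11-01).
#' @param noise_sd Optional day-to-day noise SD, degC (default 0: chamber
#'   set points).
#' @return List of [temperature_series()], coldest site first.
#' @export
make_regimes <- function(n_sites = 10, seed = 1L,
                         start_date = as.Date("2010-11-01"),
                         noise_sd = 0) {
  stopifnot(n_sites >= 1)
  set.seed(seed)
  # winter minima from severe (-12 degC) to mild (8 degC)
  minima <- seq(-12, 8, length.out = n_sites)
  dates <- as.Date(start_date) + 0:179
  lapply(seq_len(n_sites), function(s) {
    m <- minima[s]
    seg <- c(seq(14, m, length.out = 6),      # decline, 60 d in 10-d steps
             rep(m, 6),                       # hold, 60 d
             seq(m, 15, length.out = 6))      # rise, 60 d
    temps <- rep(seg, each = 10)[1:180]
    if (noise_sd > 0) temps <- temps + stats::rnorm(180, 0, noise_sd)
    temperature_series(sprintf("regime_%02d", s), dates, temps,
                       latitude = 45 - (s - 1) * 2.5)
  })
}

#' Simulate the laboratory winter-survival experiment
#'
#' For every regime and sampling point (every `sample_every_days` days,
#' `n_samples` points) and every stage, draws
#' `n_survived ~ Binomial(n, a*exp(b*LTDD_so_far))` where LTDD accumulates
#' from the regime start to the sampling day. Samples are independent (no
#' individual is measured twice). With `n_per_sample = Inf` the exact
#' survival proportion is returned (noiseless mode).
#'
#' @param regimes List of [temperature_series()] (see [make_regimes()]).
#' @param truth A [truth_params()].
#' @param n_per_sample Named integer vector of individuals per stage per
#'   sampling point (default `c(larva = 55, pupa = 65)`), or `Inf`.
#' @param sample_every_days Days between sampling points (default 10).
#' @param n_samples Number of sampling points per regime (default 11).
#' @param seed Integer seed.
#' @param config A [thermal_config()].
#' @return Data frame of observations with columns `site_id`, `stage`,
#'   `setting`, `exposure_start`, `exposure_end`, `n_exposed`, `n_survived`,
#'   `survival`, `LTDD`, `MinDTmean`, `DTmean`, `exposure_days`.
#' @export
simulate_survival_experiment <- function(regimes, truth = truth_params(),
                                         n_per_sample = c(larva = 55,
                                                          pupa = 65),
                                         sample_every_days = 10,
                                         n_samples = 11, seed = 1L,
                                         config = thermal_config()) {
  set.seed(seed)
  a <- truth$survival[["a"]]; b <- truth$survival[["b"]]
  noiseless <- any(!is.finite(n_per_sample))
  stages <- if (is.null(names(n_per_sample)))
    paste0("stage", seq_along(n_per_sample)) else names(n_per_sample)
  rows <- list()
  for (reg in regimes) {
    start <- reg$dates[1]
    for (k in seq_len(n_samples)) {
      end <- start + k * sample_every_days - 1
      lt <- ltdd(reg, start = start, end = end, config = config)
      mm <- min_dt_mean(reg, start, end)
      dm <- dt_mean_exposure(reg, start, end)
      p <- min(1, max(0, a * exp(b * lt)))
      for (si in seq_along(stages)) {
        n <- n_per_sample[si]
        surv <- if (noiseless) p else stats::rbinom(1, n, p) / n
        rows[[length(rows) + 1L]] <- data.frame(
          site_id = reg$site_id, stage = stages[si], setting = "lab",
          exposure_start = start, exposure_end = end,
          n_exposed = if (noiseless) NA_integer_ else as.integer(n),
          n_survived = if (noiseless) NA_integer_ else
            as.integer(round(surv * n)),
          survival = surv, LTDD = lt, MinDTmean = mm,
          DTmean = dm$mean, exposure_days = dm$days)
      }
    }
  }
  do.call(rbind, rows)
}

#' Simulate field survival observations from a survival law
#'
#' Emulates the field validation design: cages of individuals exposed at
#' sites spanning a temperature gradient, collected after 1-4 months, with
#' binomial survival around the model law evaluated at the site's
#' accumulated LTDD.
#'
#' @param regimes List of [temperature_series()] used as site climates.
#' @param truth A [truth_params()].
#' @param n_per_cage Individuals per cage (default 30).
#' @param n_cages Cages collected per site x month x stage (default 2).
#' @param months Exposure durations in 30-day months (default 1:4).
#' @param stages Stage labels (default larva, pupa, adult).
#' @param seed Integer seed.
#' @param config A [thermal_config()].
#' @return Data frame shaped like [simulate_survival_experiment()] output
#'   with `setting = "field_plant"`.
#' @export
simulate_field_experiment <- function(regimes, truth = truth_params(),
                                      n_per_cage = 30, n_cages = 2,
                                      months = 1:4,
                                      stages = c("larva", "pupa", "adult"),
                                      seed = 1L,
                                      config = thermal_config()) {
  set.seed(seed)
  a <- truth$survival[["a"]]; b <- truth$survival[["b"]]
  rows <- list()
  for (reg in regimes) {
    start <- reg$dates[1]
    for (mo in months) {
      end <- start + mo * 30 - 1
      if (end > max(reg$dates)) next
      lt <- ltdd(reg, start = start, end = end, config = config)
      mm <- min_dt_mean(reg, start, end)
      dm <- dt_mean_exposure(reg, start, end)
      p <- min(1, max(0, a * exp(b * lt)))
      for (st in stages) for (cg in seq_len(n_cages)) {
        surv <- stats::rbinom(1, n_per_cage, p) / n_per_cage
        rows[[length(rows) + 1L]] <- data.frame(
          site_id = reg$site_id, stage = st, setting = "field_plant",
          exposure_start = start, exposure_end = end,
          n_exposed = as.integer(n_per_cage),
          n_survived = as.integer(round(surv * n_per_cage)),
          survival = surv, LTDD = lt, MinDTmean = mm,
          DTmean = dm$mean, exposure_days = dm$days)
      }
    }
  }
  do.call(rbind, rows)
}

#' Simulate a small latitudinally structured climate grid
#'
#' Daily mean temperatures built from a latitudinal gradient, a
#' hemisphere-phased seasonal cycle (amplitude growing with |latitude|), a
#' linear warming trend and day-to-day noise; both hemispheres are
#' represented. The accompanying host mask is a smooth pseudo-random field
#' in [0, 1]. Days cover January 1 of the first year through June 30 of the
#' year after the last, so every annual window labelled within `years` is
#' covered at all latitudes.
#'
#' @param n_lat,n_lon Grid dimensions. The default 31 latitude rows over
#' -45..45 degrees give a 3-degree spacing, fine enough that the marginal
#' survival belt (a few degrees wide under the default survival law) is
#' populated in both hemispheres.
#' @param years Integer vector of window label years.
#' @param truth A [truth_params()] (uses `grid_trend`, `grid_noise_sd`).
#' @param seed Integer seed.
#' @param lat_range Latitude span of the grid (default -45..45).
#' @return List with `grid` (a [climate_grid()]) and `host` (matrix).
#' @export
simulate_climate_grid <- function(n_lat = 31, n_lon = 4,
                                  years = 1967:1976,
                                  truth = truth_params(), seed = 1L,
                                  lat_range = c(-45, 45)) {
  stopifnot(n_lat >= 1, n_lon >= 1)
  set.seed(seed)
  lats <- if (n_lat == 1) mean(lat_range) else
    seq(lat_range[1], lat_range[2], length.out = n_lat)
  lons <- seq(0, by = 1, length.out = n_lon)
  y0 <- min(years)
  dates <- seq(as.Date(sprintf("%d-01-01", y0)),
               as.Date(sprintf("%d-06-30", max(years) + 1L)), by = "day")
  doy <- as.integer(format(dates, "%j"))
  yr_frac <- as.numeric(dates - dates[1]) / 365.25
  tm <- array(NA_real_, c(n_lat, n_lon, length(dates)))
  for (i in seq_len(n_lat)) {
    la <- lats[i]
    amp <- 2 + 0.25 * abs(la)
    # warm peak mid-July in the north, mid-January in the south
    phase <- if (la >= 0) 196 else 15
    base <- 27 - 0.45 * abs(la) +
      amp * cos(2 * pi * (doy - phase) / 365.25) +
      truth$grid_trend * yr_frac
    for (j in seq_len(n_lon)) {
      cell_off <- stats::rnorm(1, 0, 0.5)
      tm[i, j, ] <- base + cell_off +
        stats::rnorm(length(dates), 0, truth$grid_noise_sd)
    }
  }
  grid <- climate_grid(lats, lons, dates, tm)
  # smooth pseudo-random host field: low-order trigonometric surface
  cf <- stats::rnorm(6)
  f <- outer(seq_len(n_lat) / n_lat, seq_len(n_lon) / n_lon,
             function(u, v) cf[1] * sin(2 * pi * u) + cf[2] * cos(2 * pi * v) +
               cf[3] * sin(2 * pi * (u + v)) + cf[4] * cos(4 * pi * u) +
               cf[5] * sin(4 * pi * v) + cf[6])
  host <- (f - min(f)) / max(max(f) - min(f), 1e-12)
  list(grid = grid, host = host)
}

#' Simulate pesticide-resistance records with known structure
#'
#' Places sampling sites on unmasked grid cells, annotates each site with
#' its true 5-year LTDD/ETDD/overwintering type (using the truth survival
#' law), and draws
#' `ln RR = mu + ow_effect + pesticide_effect + etdd_slope*ETDD +
#' site-year effect + residual`. LC50s and 95 % CIs are generated so that
#' the pooled-variance chain recovers the per-record generating variance
#' exactly: each record's target variance `v` is split evenly between the
#' field and susceptible terms, and each SE is encoded into a symmetric CI.
#' A configurable fraction of CIs is blanked to exercise imputation.
#'
#' @param n_records Number of records (the source design has 1806).
#' @param truth A [truth_params()].
#' @param grid_sim Output of [simulate_climate_grid()].
#' @param seed Integer seed.
#' @param n_sites Number of distinct sampling sites (default 120).
#' @param n_pesticides Number of pesticide varieties (default 15).
#' @param missing_ci_frac Fraction of records with CIs blanked
#'   (default 0.15).
#' @param null_effects Zero out the overwintering-type and ETDD effects
#'   (for type-I error simulations).
#' @param config A [thermal_config()].
#' @return Data frame of resistance records (I/O schema of
#'   [read_resistance_records()]) plus the true annotations `ow_type_true`,
#'   `etdd_5yr_true`, `ltdd_5yr_true` and `true_log_rr`.
#' @export
simulate_resistance_records <- function(n_records = 1806,
                                        truth = truth_params(),
                                        grid_sim, seed = 1L,
                                        n_sites = 120, n_pesticides = 15,
                                        missing_ci_frac = 0.15,
                                        null_effects = FALSE,
                                        config = thermal_config()) {
  set.seed(seed)
  grid <- grid_sim$grid; host <- grid_sim$host
  model <- structure(list(
    spec = survival_spec("LTDD", "exponential"),
    coefficients = c(a = truth$survival[["a"]], b = truth$survival[["b"]]),
    k = 2L), class = "ows_fit")
  ok_cells <- which(host >= 0.3, arr.ind = TRUE)
  if (nrow(ok_cells) == 0) ok_cells <- which(host >= 0, arr.ind = TRUE)
  pick <- ok_cells[sample.int(nrow(ok_cells), n_sites, replace = TRUE), ,
                   drop = FALSE]
  grid_years <- sort(unique(as.integer(format(grid$dates, "%Y"))))
  yr_lo <- min(grid_years) + 5L
  yr_hi <- max(grid_years) - 1L
  site_tab <- data.frame(site = seq_len(n_sites),
                         i = pick[, 1], j = pick[, 2],
                         latitude = grid$lats[pick[, 1]],
                         longitude = grid$lons[pick[, 2]])
  pest_eff <- stats::rnorm(n_pesticides, 0, truth$pesticide_sd)
  ow_eff <- if (null_effects)
    c(transient = 0, marginal = 0, permanent = 0) else truth$ow_effect
  etdd_slope <- if (null_effects) 0 else truth$etdd_slope

  s_idx <- sample.int(n_sites, n_records, replace = TRUE)
  year <- sample(seq(yr_lo, yr_hi), n_records, replace = TRUE)
  pest <- sample.int(n_pesticides, n_records, replace = TRUE)

  # true site-year annotations from the generating survival law, via
  # cached per-year degree-day grids
  need_years <- sort(unique(unlist(lapply(
    unique(year), function(y) (y - 5L):(y - 1L)))))
  tabs <- .grid_annual_tables(grid, need_years, config)
  key <- paste(s_idx, year)
  ann <- new.env(parent = emptyenv())
  for (u in which(!duplicated(key))) {
    si <- s_idx[u]; yr <- year[u]
    i <- site_tab$i[si]; j <- site_tab$j[si]
    yrs <- as.character((yr - 5L):(yr - 1L))
    lt <- vapply(yrs, function(y) tabs$ltdd[[y]][i, j], numeric(1))
    et <- vapply(yrs, function(y) tabs$etdd[[y]][i, j], numeric(1))
    sv <- mean(predict(model, lt))
    ow <- if (sv >= 0.05) "permanent" else if (sv >= 0.01) "marginal"
          else "transient"
    assign(key[u], list(lt = mean(lt), et = mean(et), ow = ow,
                        re = stats::rnorm(1, 0, truth$site_year_sd)),
           envir = ann)
  }
  av <- lapply(key, get, envir = ann)
  ltdd_true <- vapply(av, `[[`, numeric(1), "lt")
  etdd_true <- vapply(av, `[[`, numeric(1), "et")
  ow_true <- vapply(av, `[[`, character(1), "ow")
  re <- vapply(av, `[[`, numeric(1), "re")

  ln_rr <- truth$mu + unname(ow_eff[ow_true]) + pest_eff[pest] +
    etdd_slope * etdd_true + re +
    stats::rnorm(n_records, 0, truth$residual_sd)
  rr <- exp(ln_rr)

  # encode the per-record sampling variance into CIs (even split)
  v <- stats::rlnorm(n_records,
                     log(truth$v_mean) - truth$v_sdlog^2 / 2,
                     truth$v_sdlog)
  n_field <- sample(120:600, n_records, replace = TRUE)
  n_sus <- sample(120:600, n_records, replace = TRUE)
  lc50_sus <- stats::rlnorm(n_records, 0, 1)
  lc50_field <- lc50_sus * rr
  se_f <- lc50_field * sqrt(n_field * v / 2)
  se_s <- lc50_sus * sqrt(n_sus * v / 2)
  rec <- data.frame(
    pesticide = sprintf("pesticide_%02d", pest),
    moa_group = sprintf("moa_%d", (pest - 1L) %% 5L + 1L),
    latitude = site_tab$latitude[s_idx],
    longitude = site_tab$longitude[s_idx],
    year = year,
    lc50_field = lc50_field,
    ci_field_lo = lc50_field - 1.96 * se_f,
    ci_field_hi = lc50_field + 1.96 * se_f,
    n_field = n_field,
    lc50_susceptible = lc50_sus,
    ci_sus_lo = lc50_sus - 1.96 * se_s,
    ci_sus_hi = lc50_sus + 1.96 * se_s,
    n_susceptible = n_sus,
    rr = rr,
    ow_type_true = ow_true,
    etdd_5yr_true = etdd_true,
    ltdd_5yr_true = ltdd_true,
    true_log_rr = ln_rr,
    v_true = v)
  if (missing_ci_frac > 0) {
    drop <- sample.int(n_records, round(missing_ci_frac * n_records))
    rec[drop, c("ci_field_lo", "ci_field_hi", "ci_sus_lo", "ci_sus_hi")] <-
      NA_real_
  }
  rec
}

#' Simulate records with a known linear conditional quantile
#'
#' Heteroscedastic draws `y = a + b*x + (s0 + s1*x)*Z`, `Z ~ N(0,1)`, whose
#' tau-quantile line is exactly `a + s0*q_tau + (b + s1*q_tau)*x` with
#' `q_tau` the standard-normal tau-quantile. Used for quantile-regression
#' recovery tests; `y` is on the log10(RR) scale.
#'
#' @param n Number of records.
#' @param a,b Median-line intercept and slope.
#' @param s0,s1 Noise-scale intercept and slope (both >= 0, `s0 > 0`).
#' @param x_max Predictor range upper bound (x ~ Uniform(0, x_max)).
#' @param seed Integer seed.
#' @return Data frame with `ltdd_5yr`, `rr`, and attributes
#'   `true_slope(tau)`/`true_intercept(tau)` accessor via
#'   `attr(, "quantile_line")` (a function of tau).
#' @export
simulate_quantile_records <- function(n = 500, a = 0.5, b = 1.5e-3,
                                      s0 = 0.3, s1 = 1e-3, x_max = 1500,
                                      seed = 1L) {
  set.seed(seed)
  x <- stats::runif(n, 0, x_max)
  y <- a + b * x + (s0 + s1 * x) * stats::rnorm(n)
  df <- data.frame(ltdd_5yr = x, rr = 10^y)
  attr(df, "quantile_line") <- function(tau) {
    q <- stats::qnorm(tau)
    c(intercept = a + s0 * q, slope = b + s1 * q)
  }
  df
}
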