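test_that("uniform warm grid accumulates no LTDD", {
  g <- const_grid(20)
  expect_true(all(annual_ltdd_grid(g, 2000) == 0))
})

test_that("grid LTDD equals the site-level computation per cell", {
  set.seed(5)
  lats <- c(-35, 10, 42)
  lons <- c(100, 101)
  dates <- seq(as.Date("1999-01-01"), as.Date("2002-06-30"), by = "day")
  tm <- array(runif(length(lats) * length(lons) * length(dates), -15, 30),
              c(length(lats), length(lons), length(dates)))
  g <- climate_grid(lats, lons, dates, tm)
  lt <- annual_ltdd_grid(g, 2000)
  for (i in seq_along(lats)) for (j in seq_along(lons)) {
    s <- temperature_series("c", dates, tm[i, j, ], latitude = lats[i])
    expect_equal(lt[i, j], ltdd(s, annual_window_for(lats[i], 2000)),
                 tolerance = 1e-9)
  }
  et <- annual_etdd_grid(g, 2000)
  for (i in seq_along(lats)) for (j in seq_along(lons)) {
    s <- temperature_series("c", dates, tm[i, j, ], latitude = lats[i])
    expect_equal(et[i, j], etdd(s, 2000), tolerance = 1e-9)
  }
})

test_that("survival grid composes LTDD with the model and averages years", {
  m <- known_exp_model()
  g <- const_grid(20, years = 2000:2005)
  sv <- survival_grid(g, m, 2001)
  expect_true(all(sv == 0.9))  # LTDD = 0 everywhere -> intercept a
  sv5 <- survival_grid(g, m, 2001:2005)
  expect_equal(sv5, sv)
  # warmer grid never lowers survival
  set.seed(8)
  dates <- seq(as.Date("2000-01-01"), as.Date("2001-06-30"), by = "day")
  tm <- array(runif(2 * 2 * length(dates), -10, 25),
              c(2, 2, length(dates)))
  g1 <- climate_grid(c(-10, 10), c(0, 1), dates, tm)
  g2 <- warming_scenario(g1, 3)
  expect_true(all(survival_grid(g2, m, 2000) >= survival_grid(g1, m, 2000)))
  bad <- structure(list(spec = survival_spec("MinDTmean", "linear"),
                        coefficients = c(a = 1, b = 0), k = 2L),
                   class = "ows_fit")
  expect_error(survival_grid(g1, bad, 2000), "LTDD")
})

test_that("classification respects thresholds, mask override and partition", {
  sv <- matrix(c(0.05, 0.01, 0.009, 0.2), 2, 2)
  host <- matrix(c(0.3, 0.9, 0.9, 0.29), 2, 2)
  m <- classify_overwintering(sv, host, lats = c(0, 1), lons = c(0, 1))
  expect_equal(m$owclass[1, 1], "permanent")   # both boundaries inclusive
  expect_equal(m$owclass[2, 1], "marginal")    # 1% inclusive
  expect_equal(m$owclass[1, 2], "transient")   # < 1%
  expect_equal(m$owclass[2, 2], "masked")      # host 0.29 overrides
  expect_true(all(m$owclass %in% c("permanent", "marginal", "transient",
                                   "masked")))
  # exhaustive and exclusive on random survival values
  set.seed(2)
  sv2 <- matrix(runif(100), 10, 10)
  m2 <- classify_overwintering(sv2, NULL, lats = 1:10, lons = 1:10)
  expect_equal(sum(m2$owclass == "permanent") +
                 sum(m2$owclass == "marginal") +
                 sum(m2$owclass == "transient"), 100)
  expect_error(classify_overwintering(sv, host[1, , drop = FALSE],
                                      lats = c(0, 1), lons = c(0, 1)),
               "geometry")
})

test_that("cell areas follow spherical cos-latitude weighting", {
  expect_equal(cell_area_km2(0), 111.195^2, tolerance = 1e-12)
  expect_equal(cell_area_km2(0), 12364.3, tolerance = 1e-4)
  expect_equal(cell_area_km2(60), cell_area_km2(0) / 2, tolerance = 1e-12)
  expect_equal(cell_area_km2(90), 0, tolerance = 1e-10)
  expect_error(cell_area_km2(91), "latitude")
})

test_that("overwinter area counts and weights qualifying cells", {
  sv <- matrix(c(0.1, 0.02, 0.002, 0.5), 2, 2)
  m <- classify_overwintering(sv, NULL, lats = c(0, 60), lons = c(0, 1))
  a5 <- overwinter_area(m, 0.05)
  a1 <- overwinter_area(m, 0.01)
  expect_equal(a5$cells, 2)
  expect_equal(a1$cells, 3)
  expect_gte(a1$cells, a5$cells)  # nested cutoffs nest
  expect_gte(a1$area_km2, a5$area_km2)
  # one equator cell
  m1 <- classify_overwintering(matrix(0.1), NULL, lats = 0, lons = 0)
  expect_equal(overwinter_area(m1, 0.05)$area_km2, cell_area_km2(0))
  # empty qualifying set
  m0 <- classify_overwintering(matrix(0.001), NULL, lats = 0, lons = 0)
  expect_equal(overwinter_area(m0, 0.05), list(cells = 0L, area_km2 = 0))
})

test_that("permanent + marginal areas never exceed the unmasked total", {
  set.seed(13)
  sv <- matrix(runif(64), 8, 8)
  host <- matrix(runif(64), 8, 8)
  m <- classify_overwintering(sv, host, lats = seq(-35, 35, by = 10),
                              lons = 1:8)
  unmasked <- sum(m$owclass != "masked")
  expect_lte(sum(m$owclass == "permanent") + sum(m$owclass == "marginal"),
             unmasked)
})

test_that("warming scenarios shift temperatures and never shrink range", {
  set.seed(31)
  dates <- seq(as.Date("2000-01-01"), as.Date("2001-06-30"), by = "day")
  lats <- seq(-40, 40, by = 20)
  tm <- array(rep(20 - 0.6 * abs(lats), length(dates) * 3) +
                rnorm(5 * 3 * length(dates), 0, 2),
              c(5, 3, length(dates)))
  g <- climate_grid(lats, 1:3, dates, tm)
  expect_equal(warming_scenario(g, 0)$tmean, g$tmean)
  m <- known_exp_model()
  areas <- sapply(c(0, 1, 2, 4, 6), function(d) {
    sv <- survival_grid(warming_scenario(g, d), m, 2000)
    mm <- classify_overwintering(sv, NULL, lats, 1:3)
    overwinter_area(mm, 0.05)$area_km2
  })
  expect_true(all(diff(areas) >= 0))
  # big enough delta removes all cold: LTDD zero everywhere
  g_hot <- warming_scenario(g, 60)
  expect_true(all(annual_ltdd_grid(g_hot, 2000) == 0))
})

test_that("expansion series is zero under stationary climate", {
  g <- const_grid(5, lats = c(-10, 10), lons = c(0, 1), years = 2000:2005)
  m <- known_exp_model()
  es <- expansion_series(g, m, NULL, years = 2000:2004,
                         baseline_year = 2000)
  expect_true(all(es$yearly$delta_ge5 == 0))
  expect_true(all(es$yearly$delta_ge1 == 0))
  expect_true(all(es$blocks$delta_ge5 == 0))
  expect_error(expansion_series(g, m, NULL, years = 2001:2004,
                                baseline_year = 2000), "baseline")
})

test_that("warming trend expands the range on the synthetic grid", {
  sim <- simulate_climate_grid(21, 2, years = 1967:1980,
                               truth = truth_params(grid_trend = 0.12,
                                                    grid_noise_sd = 0.5),
                               seed = 14)
  m <- known_exp_model()
  es <- expansion_series(sim$grid, m, NULL, years = c(1967, 1979),
                         baseline_year = 1967)
  expect_gte(es$yearly$delta_ge5[es$yearly$year == 1979], 0)
})

test_that("single-cell marginal belt trend equals that cell's LTDD trend", {
  # build a one-cell grid whose survival sits in the marginal band
  m <- known_exp_model()
  # survival 0.03 -> LTDD = log(0.9/0.03)/0.005 = 680.3; need constant temp
  # T with 11 - T deficits over the southern window: T = 11 - 680.3/365
  tt <- 11 - log(0.9 / 0.03) / 0.005 / 365
  dates <- seq(as.Date("2000-01-01"), as.Date("2004-12-31"), by = "day")
  yr <- as.integer(format(dates, "%Y")) - 2000L
  temps <- tt + 0.1 * yr  # warming: LTDD declines ~36.5 degC-day/yr
  tm <- array(temps, c(1, 1, length(dates)))
  g <- climate_grid(-20, 5, dates, tm)
  tr <- marginal_belt_trend(g, m, NULL, years = 2000:2004,
                            baseline_year = 2000)
  expect_equal(tr$n_cells, 1)
  expect_equal(tr$slope, -0.1 * 365, tolerance = 0.02)
  expect_gt(tr$r2, 0.99)
  expect_lt(tr$p, 0.01)
  # warm grid has no marginal belt
  expect_error(marginal_belt_trend(const_grid(20, years = 2000:2002), m,
                                   NULL, years = 2000:2001,
                                   baseline_year = 2000),
               "empty marginal belt")
})

test_that("overwinter map CSV export carries class codes", {
  sv <- matrix(c(0.1, 0.02, 0.005, 0.3), 2, 2)
  host <- matrix(c(1, 1, 1, 0.1), 2, 2)
  m <- classify_overwintering(sv, host, lats = c(0, 10), lons = c(5, 6))
  f <- tempfile(fileext = ".csv")
  write_overwinter_map(m, f)
  df <- read.csv(f)
  expect_setequal(df$class_code, c(2L, 1L, 0L, 9L))
  expect_equal(nrow(df), 4)
  unlink(f)
})
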