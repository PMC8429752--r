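test_that("SE from CI follows the 3.92 rule", {
  expect_equal(se_from_ci(1.0, 4.92), 1.0)
  expect_equal(se_from_ci(5, 5), 0)
  expect_equal(se_from_ci(0, 7.84), 2.0)
  expect_error(se_from_ci(2, 1), "inverted")
})

test_that("pooled variance composes the two population terms", {
  # SE_f = 2, n_f = 4, LC50_f = 1, susceptible term zero -> 4/(4*1) = 1
  r <- data.frame(lc50_field = 1, ci_field_lo = 1 - 1.96 * 2,
                  ci_field_hi = 1 + 1.96 * 2, n_field = 4,
                  lc50_susceptible = 1, ci_sus_lo = 1, ci_sus_hi = 1,
                  n_susceptible = 10)
  expect_equal(pooled_variance(r), 1.0)
  # both SEs zero -> 0
  r0 <- basic_records(2, se_f = 0, se_s = 0)
  expect_equal(pooled_variance(r0), 0)
  # symmetry: swapping the two populations' triples leaves V unchanged
  r1 <- data.frame(lc50_field = 3, ci_field_lo = 3 - 1.96 * 0.5,
                   ci_field_hi = 3 + 1.96 * 0.5, n_field = 7,
                   lc50_susceptible = 1.2, ci_sus_lo = 1.2 - 1.96 * 0.2,
                   ci_sus_hi = 1.2 + 1.96 * 0.2, n_susceptible = 9)
  r2 <- data.frame(lc50_field = 1.2, ci_field_lo = 1.2 - 1.96 * 0.2,
                   ci_field_hi = 1.2 + 1.96 * 0.2, n_field = 9,
                   lc50_susceptible = 3, ci_sus_lo = 3 - 1.96 * 0.5,
                   ci_sus_hi = 3 + 1.96 * 0.5, n_susceptible = 7)
  expect_equal(pooled_variance(r1), pooled_variance(r2))
})

test_that("prognostic imputation fills with the mean of complete entries", {
  out <- impute_variance(c(1, NA, 3))
  expect_equal(out$v, c(1, 2, 3))
  expect_equal(out$imputed, c(FALSE, TRUE, FALSE))
  out2 <- impute_variance(c(0.5, 0.7))
  expect_equal(out2$v, c(0.5, 0.7))
  expect_false(any(out2$imputed))
  out3 <- impute_variance(c(NA, 4, NA))
  expect_equal(out3$v, c(4, 4, 4))
  expect_error(impute_variance(c(NA_real_, NA_real_)), "complete")
})

test_that("effect-size chain matches hand composition to 1e-12", {
  set.seed(17)
  n <- 50
  rec <- data.frame(
    lc50_field = runif(n, 0.5, 20), n_field = sample(50:500, n, TRUE),
    lc50_susceptible = runif(n, 0.1, 2),
    n_susceptible = sample(50:500, n, TRUE))
  sef <- runif(n, 0.01, 1); ses <- runif(n, 0.01, 0.5)
  rec$ci_field_lo <- rec$lc50_field - 1.96 * sef
  rec$ci_field_hi <- rec$lc50_field + 1.96 * sef
  rec$ci_sus_lo <- rec$lc50_susceptible - 1.96 * ses
  rec$ci_sus_hi <- rec$lc50_susceptible + 1.96 * ses
  rec$rr <- rec$lc50_field / rec$lc50_susceptible
  es <- effect_sizes(rec)
  for (i in seq_len(n)) {
    se_f_h <- (rec$ci_field_hi[i] - rec$ci_field_lo[i]) / (2 * 1.96)
    se_s_h <- (rec$ci_sus_hi[i] - rec$ci_sus_lo[i]) / (2 * 1.96)
    v_h <- se_f_h^2 / (rec$n_field[i] * rec$lc50_field[i]^2) +
      se_s_h^2 / (rec$n_susceptible[i] * rec$lc50_susceptible[i]^2)
    w_h <- 1 / sqrt(v_h)
    expect_equal(es$v[i], v_h, tolerance = 1e-12)
    expect_equal(es$w[i], w_h, tolerance = 1e-12)
    expect_equal(es$wlog_rr[i], log(rec$rr[i]) * w_h, tolerance = 1e-12)
  }
  expect_false(any(es$imputed_v))
})

test_that("effect-size identities hold at the reference points", {
  r <- basic_records(c(1, exp(1)))
  # force v = 4 then 1 by constructing SEs
  es <- effect_sizes(r)
  expect_equal(es$log_rr[1], 0)
  expect_equal(es$wlog_rr[1], 0)
  expect_true(all(sign(es$wlog_rr) == sign(es$log_rr)))
  expect_error(effect_sizes(transform(r, rr = c(-1, 1))), "positive")
  # w = 1/sqrt(v): v = 4 gives w = 0.5
  r2 <- data.frame(lc50_field = 1, ci_field_lo = 1 - 1.96 * 2,
                   ci_field_hi = 1 + 1.96 * 2, n_field = 1,
                   lc50_susceptible = 1, ci_sus_lo = 1, ci_sus_hi = 1,
                   n_susceptible = 1, rr = exp(1))
  es2 <- effect_sizes(r2)
  expect_equal(es2$w, 0.5)
  expect_equal(es2$wlog_rr, 0.5)
})

test_that("zero variances are floored, not infinite-weighted", {
  r <- basic_records(c(2, 3, 4), se_f = 0.5, se_s = 0.5)
  r$ci_field_lo[3] <- r$ci_field_hi[3] <- r$lc50_field[3]
  r$ci_sus_lo[3] <- r$ci_sus_hi[3] <- r$lc50_susceptible[3]
  es <- effect_sizes(r)
  expect_true(es$v_floored[3])
  expect_true(all(is.finite(es$w)))
})

test_that("resistance levels partition (0, Inf) at the quoted boundaries", {
  expect_equal(as.character(classify_resistance(c(0.5, 1, 1.0001, 9.99))),
               c("susceptible", "susceptible", "low", "low"))
  expect_equal(as.character(classify_resistance(c(10, 99.9, 100, 999, 1000,
                                                  5e4))),
               c("moderate", "moderate", "high", "high", "extreme",
                 "extreme"))
  set.seed(19)
  rr <- 10^runif(500, -2, 5)
  lev <- classify_resistance(rr)
  expect_false(anyNA(lev))          # exhaustive
  expect_equal(length(lev), 500)    # one label each
  expect_error(classify_resistance(0), "positive")
})

test_that("weighted mean RR is a weighted geometric mean with invariances", {
  r <- data.frame(log_rr = log(c(4, 4, 4)), w = c(1, 2, 5),
                  ow_type = "permanent")
  expect_equal(unname(weighted_mean_rr(r)), 4)
  r2 <- data.frame(log_rr = log(c(2, 8)), w = c(1, 1), ow_type = "x")
  expect_equal(unname(weighted_mean_rr(r2)), 4)  # geometric mean
  # order and uniform weight rescaling do not matter
  set.seed(23)
  r3 <- data.frame(log_rr = rnorm(30), w = runif(30, 0.5, 3),
                   ow_type = sample(c("a", "b"), 30, TRUE))
  base <- weighted_mean_rr(r3)
  expect_equal(weighted_mean_rr(r3[sample(30), ]), base)
  r3$w <- r3$w * 17
  expect_equal(weighted_mean_rr(r3), base)
})

test_that("level frequencies sum to one per group", {
  r <- data.frame(rr = c(0.5, 5, 50, 500, 5000, 2),
                  ow_type = c(rep("permanent", 5), "transient"))
  fr <- level_frequencies(r)
  expect_equal(unname(rowSums(fr)), c(1, 1))
  expect_equal(unname(fr["permanent", ]), rep(0.2, 5))
  expect_equal(unname(fr["transient", "low"]), 1)
})

test_that("site annotation matches the generator's own truth", {
  sim <- simulate_climate_grid(21, 2, years = 2000:2008, seed = 3)
  m <- known_exp_model()
  rec <- simulate_resistance_records(150, grid_sim = sim, seed = 4,
                                     n_sites = 30, n_pesticides = 5)
  ann <- annotate_sites(rec, sim$grid, m)
  expect_equal(ann$ow_type, ann$ow_type_true)
  expect_equal(ann$ltdd_5yr, ann$ltdd_5yr_true, tolerance = 1e-9)
  expect_equal(ann$etdd_5yr, ann$etdd_5yr_true, tolerance = 1e-9)
  # determinism: same site and year gives identical annotation
  dup <- which(duplicated(paste(ann$latitude, ann$longitude, ann$year)))
  if (length(dup)) {
    k <- dup[1]
    twin <- which(ann$latitude == ann$latitude[k] &
                    ann$longitude == ann$longitude[k] &
                    ann$year == ann$year[k])[1]
    expect_equal(ann$ltdd_5yr[k], ann$ltdd_5yr[twin])
  }
  # warm-site record: LTDD 0 all years -> survival = a = 0.9 -> permanent
  warm <- const_grid(25, lats = c(0, 1), lons = c(0, 1), years = 2000:2006)
  wrec <- data.frame(latitude = 0, longitude = 0, year = 2006)
  wann <- annotate_sites(wrec, warm, m)
  expect_equal(wann$ow_type, "permanent")
  expect_equal(wann$winter_survival_5yr, 0.9)
})

test_that("mixed-model Wald chi-square matches the squared z closed form", {
  # balanced two-level factor, fixed-effects-only reduction
  set.seed(29)
  n <- 120
  d <- data.frame(ow_type = rep(c("permanent", "transient"), each = n / 2),
                  pesticide = rep(c("p1", "p2"), times = n / 2),
                  etdd_5yr = rnorm(n),
                  latitude = 1, longitude = 1, year = 2000)
  d$wlog_rr <- 2 * (d$ow_type == "permanent") + rnorm(n)
  tab <- mixed_model_anova(d, interactions = FALSE, fixed_only = TRUE)
  fit <- lm(wlog_rr ~ ow_type + pesticide + etdd_5yr, data = d)
  z <- coef(fit)["ow_typetransient"] /
    sqrt(vcov(fit)["ow_typetransient", "ow_typetransient"])
  expect_equal(tab$chisq[tab$source == "ow_type"], unname(z^2),
               tolerance = 1e-8)
  expect_equal(tab$df[tab$source == "ow_type"], 1)
})

test_that("mixed model recovers an injected overwintering-type effect", {
  sim <- simulate_climate_grid(21, 2, years = 2000:2008, seed = 5)
  rec <- simulate_resistance_records(500, grid_sim = sim, seed = 6,
                                     n_sites = 60, n_pesticides = 6)
  es <- effect_sizes(rec)
  es$ow_type <- es$ow_type_true
  es$etdd_5yr <- es$etdd_5yr_true
  tab <- mixed_model_anova(es, interactions = FALSE)
  expect_lt(tab$p[tab$source == "ow_type"], 0.01)
  expect_true(all(c("ow_type", "pesticide", "etdd_5yr") %in% tab$source))
  # interaction terms appear when requested
  tab2 <- suppressMessages(mixed_model_anova(es, interactions = TRUE))
  expect_true("ow_type:pesticide" %in% tab2$source)
  expect_true("pesticide:etdd_5yr" %in% tab2$source ||
                "etdd_5yr:pesticide" %in% tab2$source)
})

test_that("quantile model recovers a known heteroscedastic quantile line", {
  d <- simulate_quantile_records(800, seed = 31)
  truth_line <- attr(d, "quantile_line")(0.85)
  qm <- quantile_model(d, tau = 0.85, n_boot = 60, seed = 1)
  expect_equal(qm$slope, unname(truth_line["slope"]),
               tolerance = 0.25)
  expect_lt(qm$p_slope, 0.05)
  expect_error(quantile_model(d[1:5, ]), "at least 10")
  # all rr equal -> slope 0
  d0 <- data.frame(ltdd_5yr = seq(0, 1000, length.out = 40), rr = 7)
  qm0 <- quantile_model(d0, tau = 0.85, n_boot = 20, seed = 2)
  expect_equal(qm0$slope, 0, tolerance = 1e-9)
})

test_that("resistance map applies the host rule then drops zero cells", {
  qm <- list(slope = 0, intercept = 2, tau = 0.85)
  lt <- matrix(c(0, 100, 200, 300), 2, 2)
  host <- matrix(c(0.9, 0.29, 0.31, 0.9), 2, 2)
  mp <- predict_resistance_map(qm, lt, host, lats = c(0, 1), lons = c(0, 1))
  expect_equal(nrow(mp), 3)              # masked cell excluded
  expect_true(all(mp$log10_rr == 2))     # zero slope -> constant
  # single cell equals scalar prediction
  qm2 <- list(slope = 0.001, intercept = 0.5)
  mp2 <- predict_resistance_map(qm2, matrix(400), matrix(0.5), 0, 0)
  expect_equal(mp2$log10_rr, 0.5 + 0.001 * 400)
  expect_error(predict_resistance_map(qm2, matrix(1), matrix(1, 2, 2),
                                      0, 0), "match")
})

test_that("publication bias detects monotone association and its reversal", {
  d <- data.frame(log_rr = 1:15, n_field = 1:15)
  pb <- publication_bias(d)
  expect_equal(pb$kendall_tau, 1)
  d2 <- data.frame(log_rr = 1:15, n_field = 15:1)
  expect_equal(publication_bias(d2)$kendall_tau, -1)
  expect_equal(nrow(pb$funnel), 15)
  d3 <- data.frame(log_rr = rep(1, 15), n_field = 1:15)
  expect_message(pb3 <- publication_bias(d3), "undefined")
  expect_true(is.na(pb3$kendall_tau))
  expect_error(publication_bias(d[1:5, ]), "at least 10")
})

test_that("record CSV round trip preserves missing fields", {
  r <- basic_records(c(2, 3))
  r$ci_field_lo[2] <- NA
  f <- tempfile(fileext = ".csv")
  write_resistance_records(r, f)
  back <- read_resistance_records(f)
  expect_equal(nrow(back), 2)
  expect_true(is.na(back$ci_field_lo[2]))
  expect_equal(back$rr, r$rr)
  unlink(f)
})
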