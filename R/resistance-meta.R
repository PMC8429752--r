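#' Standard error from a 95 % confidence interval
#'
#' `SE = (upper - lower) / (2 * 1.96)`.
#'
#' @param lower,upper CI limits (vectorized); `upper >= lower`.
#' @return Standard error(s).
#' @examples
#' se_from_ci(1, 4.92)  # 1
#' @export
se_from_ci <- function(lower, upper) {
  bad <- !is.na(lower) & !is.na(upper) & upper < lower
  if (any(bad)) stop("inverted confidence interval", call. = FALSE)
  (upper - lower) / (2 * 1.96)
}

#' Pooled variance of a log resistance ratio
#'
#' Combines the sampling uncertainty of the field and susceptible LC50s:
#' `V = SE_f^2 / (n_f * LC50_f^2) + SE_s^2 / (n_s * LC50_s^2)`,
#' with each SE derived from its 95 % CI via [se_from_ci()]. Vectorized over
#' the columns of a record data frame; any missing ingredient yields `NA`
#' (to be filled by [impute_variance()]).
#'
#' @param records Data frame with columns `lc50_field`, `ci_field_lo`,
#'   `ci_field_hi`, `n_field`, `lc50_susceptible`, `ci_sus_lo`, `ci_sus_hi`,
#'   `n_susceptible`.
#' @return Numeric vector of pooled variances (NA where incomputable).
#' @export
pooled_variance <- function(records) {
  r <- as.data.frame(records)
  se_f <- se_from_ci(r$ci_field_lo, r$ci_field_hi)
  se_s <- se_from_ci(r$ci_sus_lo, r$ci_sus_hi)
  v <- se_f^2 / (r$n_field * r$lc50_field^2) +
    se_s^2 / (r$n_susceptible * r$lc50_susceptible^2)
  bad <- (!is.na(r$lc50_field) & r$lc50_field <= 0) |
    (!is.na(r$lc50_susceptible) & r$lc50_susceptible <= 0) |
    (!is.na(r$n_field) & r$n_field <= 0) |
    (!is.na(r$n_susceptible) & r$n_susceptible <= 0)
  v[bad] <- NA_real_
  v
}

#' Prognostic imputation of missing effect-size variances
#'
#' Entries that lack a computable pooled variance (missing CI or LC50) take
#' the arithmetic mean of the complete entries' variances.
#'
#' @param v Numeric vector of pooled variances with `NA`s.
#' @return List with `v` (all filled) and `imputed` (logical flags).
#' @export
impute_variance <- function(v) {
  complete <- !is.na(v)
  if (!any(complete))
    stop("no complete entries to impute from", call. = FALSE)
  out <- v
  out[!complete] <- mean(v[complete])
  list(v = out, imputed = !complete)
}

#' Effect sizes for resistance records
#'
#' Builds the weighted log response-ratio effect size for every record:
#' `logRR = ln(rr)`, weight `w = 1/sqrt(V)`, `wlogRR = logRR * w`, where `V`
#' is the pooled variance of the record (imputed by the prognostic rule
#' where incomputable). Zero variances (zero-width CIs) would give infinite
#' weight and are floored at the 1st percentile of the complete entries'
#' variances, flagged in `v_floored`.
#'
#' @param records Data frame of resistance records; must contain `rr` > 0
#'   and the variance ingredient columns of [pooled_variance()].
#' @param v_floor_quantile Quantile of complete variances used as the floor
#'   for zero variances (default 0.01).
#' @return The input data frame with columns `log_rr`, `v`, `w`, `wlog_rr`,
#'   `imputed_v`, `v_floored` appended.
#' @export
effect_sizes <- function(records, v_floor_quantile = 0.01) {
  r <- as.data.frame(records)
  if (any(is.na(r$rr) | r$rr <= 0))
    stop("rr must be positive", call. = FALSE)
  v_raw <- pooled_variance(r)
  imp <- impute_variance(v_raw)
  v <- imp$v
  floored <- !is.na(v) & v == 0
  if (any(floored)) {
    pos <- v_raw[!is.na(v_raw) & v_raw > 0]
    if (!length(pos))
      stop("all complete variances are zero; cannot floor", call. = FALSE)
    v[floored] <- stats::quantile(pos, v_floor_quantile, names = FALSE)
  }
  r$log_rr <- log(r$rr)
  r$v <- v
  r$w <- 1 / sqrt(v)
  r$wlog_rr <- r$log_rr * r$w
  r$imputed_v <- imp$imputed
  r$v_floored <- floored
  r
}

#' Resistance level of a resistance ratio
#'
#' Five-level classification: susceptible (RR <= 1), low (1 < RR < 10),
#' moderate (10 <= RR < 100), high (100 <= RR < 1000), extreme (RR >= 1000).
#'
#' @param rr Positive resistance ratio(s).
#' @return Factor with levels `susceptible`, `low`, `moderate`, `high`,
#'   `extreme`.
#' @examples
#' classify_resistance(c(1, 5, 10, 100, 1000))
#' @export
classify_resistance <- function(rr) {
  if (any(is.na(rr) | rr <= 0)) stop("rr must be positive", call. = FALSE)
  cut(rr, breaks = c(0, 1, 10, 100, 1000, Inf),
      labels = c("susceptible", "low", "moderate", "high", "extreme"),
      right = FALSE,
      include.lowest = TRUE) -> lev
  # cut(right = FALSE) puts rr == 1 into the second bin; the susceptible
  # class is RR <= 1 (right-closed), so fix the boundary explicitly
  lev[rr <= 1] <- "susceptible"
  lev
}

#' Annotate resistance records with site climate and overwintering type
#'
#' For each record's location (nearest grid cell) and sampling year,
#' computes the mean annual LTDD and ETDD over the five annual windows
#' labelled `year-5` to `year-1` (for northern-hemisphere cells the last
#' window ends June 30 of the sampling year), the corresponding 5-year mean
#' modelled winter survival, and the overwintering type implied by the
#' survival thresholds. Records whose windows are not covered by the grid
#' are dropped with a message; the dropped count is recorded in
#' `attr(, "n_dropped")`.
#'
#' @param records Data frame with `latitude`, `longitude`, `year`.
#' @param grid A [climate_grid()].
#' @param model An LTDD-driven `ows_fit`.
#' @param config A [thermal_config()].
#' @param n_years Averaging depth (default 5).
#' @return Records with `ltdd_5yr`, `etdd_5yr`, `winter_survival_5yr`,
#'   `ow_type` columns appended.
#' @export
annotate_sites <- function(records, grid, model, config = thermal_config(),
                           n_years = 5) {
  r <- as.data.frame(records)
  ii <- vapply(r$latitude, function(la)
    which.min(abs(grid$lats - la)), integer(1))
  jj <- vapply(r$longitude, function(lo)
    which.min(abs(grid$lons - lo)), integer(1))
  need_years <- sort(unique(unlist(lapply(
    unique(r$year), function(y) (y - n_years):(y - 1L)))))
  tabs <- .grid_annual_tables(grid, need_years, config)
  # per-record 5-year means via the cached per-year grids
  out_lt <- out_et <- out_sv <- rep(NA_real_, nrow(r))
  for (k in seq_len(nrow(r))) {
    yrs <- as.character((r$year[k] - n_years):(r$year[k] - 1L))
    lt <- vapply(yrs, function(y) tabs$ltdd[[y]][ii[k], jj[k]], numeric(1))
    et <- vapply(yrs, function(y) tabs$etdd[[y]][ii[k], jj[k]], numeric(1))
    if (anyNA(lt) || anyNA(et)) next
    out_lt[k] <- mean(lt)
    out_et[k] <- mean(et)
    out_sv[k] <- mean(predict(model, lt))
  }
  ok <- !is.na(out_lt)
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    message(n_dropped, " record(s) dropped for missing climate coverage")
  r <- r[ok, , drop = FALSE]
  r$ltdd_5yr <- out_lt[ok]
  r$etdd_5yr <- out_et[ok]
  r$winter_survival_5yr <- out_sv[ok]
  r$ow_type <- ifelse(r$winter_survival_5yr >= 0.05, "permanent",
                      ifelse(r$winter_survival_5yr >= 0.01, "marginal",
                             "transient"))
  attr(r, "n_dropped") <- n_dropped
  r
}

# cache of per-year LTDD/ETDD grids; years without full coverage yield
# all-NA matrices so callers can drop affected records
.grid_annual_tables <- function(grid, years, config) {
  na_mat <- matrix(NA_real_, length(grid$lats), length(grid$lons))
  lt <- lapply(years, function(y)
    tryCatch(annual_ltdd_grid(grid, y, config), error = function(e) na_mat))
  et <- lapply(years, function(y)
    tryCatch(annual_etdd_grid(grid, y, config), error = function(e) na_mat))
  names(lt) <- names(et) <- as.character(years)
  list(ltdd = lt, etdd = et)
}

#' Weighted mean resistance ratio per overwintering type
#'
#' Weighted mean of logRR within each group, back-transformed by
#' exponentiation (a weighted geometric mean of RR), with the effect-size
#' weights `w = 1/sqrt(V)`.
#'
#' @param records Data frame with `log_rr`, `w` (see [effect_sizes()]) and a
#'   grouping column.
#' @param group Name of the grouping column (default `"ow_type"`).
#' @return Named numeric vector of weighted mean RR per group (empty groups
#'   omitted).
#' @export
weighted_mean_rr <- function(records, group = "ow_type") {
  r <- as.data.frame(records)
  vapply(split(r, r[[group]], drop = TRUE), function(g)
    exp(sum(g$w * g$log_rr) / sum(g$w)), numeric(1))
}

#' Frequencies of the five resistance levels per group
#'
#' @inheritParams weighted_mean_rr
#' @return Matrix of proportions (groups x levels), rows summing to 1.
#' @export
level_frequencies <- function(records, group = "ow_type") {
  r <- as.data.frame(records)
  lev <- classify_resistance(r$rr)
  tab <- table(r[[group]], lev)
  prop.table(tab, margin = 1)
}

#' Mixed-model Wald tests for resistance moderators
#'
#' Fits a linear mixed model of the weighted effect size (wlogRR) on
#' overwintering type and pesticide variety (fixed factors) and ETDD
#' (covariate), with a random intercept for the sampling location-by-year
#' combination (REML, via `lme4::lmer`), and evaluates each fixed term by a
#' Type-II Wald chi-square test (`car::Anova`). The two two-way interactions
#' (pesticide x overwintering type, ETDD x pesticide) are included when
#' `interactions = TRUE`; the three-way interaction is never fitted (its
#' fixed-effect matrix is rank deficient in designs like the source's).
#'
#' @param records Annotated effect-size data frame with columns `wlog_rr`,
#'   `ow_type`, `pesticide`, `etdd_5yr`, `latitude`, `longitude`, `year`.
#' @param interactions Include the two two-way interactions (default TRUE).
#' @param fixed_only Drop the random term and fit ordinary least squares
#'   (Wald chi-square per term via `car::Anova` on the linear model); used
#'   for closed-form checks and degenerate designs.
#' @return Data frame with columns `source`, `chisq`, `df`, `p`; the fitted
#'   model in `attr(, "model")`, and `attr(, "singular")` flagging singular
#'   random-effect fits.
#' @export
mixed_model_anova <- function(records, interactions = TRUE,
                              fixed_only = FALSE) {
  r <- as.data.frame(records)
  r$ow_type <- factor(r$ow_type)
  r$pesticide <- factor(r$pesticide)
  if (nlevels(r$ow_type) < 2 || nlevels(r$pesticide) < 2)
    stop("need at least 2 levels per fixed factor", call. = FALSE)
  r$site_year <- interaction(r$latitude, r$longitude, r$year, drop = TRUE)
  # standardize the degree-day covariate: same Wald tests, better-scaled
  # optimization (ETDD is in the thousands while wlogRR is order 1)
  if (stats::sd(r$etdd_5yr) > 0)
    r$etdd_5yr <- as.numeric(scale(r$etdd_5yr))
  rhs <- "ow_type + pesticide + etdd_5yr"
  if (interactions)
    rhs <- paste(rhs, "+ ow_type:pesticide + etdd_5yr:pesticide")
  singular <- FALSE
  if (fixed_only) {
    fit <- stats::lm(stats::as.formula(paste("wlog_rr ~", rhs)), data = r)
    an <- car::Anova(fit, type = 2)
    an <- an[!rownames(an) %in% c("(Intercept)", "Residuals"), , drop = FALSE]
    # Wald chi-square per term: F x Df (equals the squared z for 1-df terms)
    tab <- data.frame(source = rownames(an), chisq = an$`F value` * an$Df,
                      df = an$Df,
                      p = stats::pchisq(an$`F value` * an$Df, an$Df,
                                        lower.tail = FALSE))
  } else {
    fml <- stats::as.formula(paste("wlog_rr ~", rhs, "+ (1 | site_year)"))
    fit <- lme4::lmer(fml, data = r, REML = TRUE)
    singular <- lme4::isSingular(fit)
    if (singular)
      message("singular random-effect fit; Wald tests reported anyway")
    an <- car::Anova(fit, type = 2)
    tab <- data.frame(source = rownames(an), chisq = an$Chisq,
                      df = an$Df, p = an$`Pr(>Chisq)`)
  }
  rownames(tab) <- NULL
  attr(tab, "model") <- fit
  attr(tab, "singular") <- singular
  tab
}

#' Quantile regression of resistance on LTDD
#'
#' Linear tau-quantile regression of log10(rr) on the 5-year mean LTDD,
#' fitted by pinball-loss minimization ([fit_quantile_line()]). The default
#' tau = 0.85 targets the top-15 % resistance level. The two-sided p-value
#' of the slope is computed from a case-resampling bootstrap standard error
#' and a t reference distribution with n - 2 degrees of freedom.
#'
#' @param records Data frame with `rr` and `ltdd_5yr`.
#' @param tau Quantile level (default 0.85).
#' @param n_boot Bootstrap replicates for the slope SE (default 200).
#' @param seed Integer seed for the bootstrap.
#' @return List with `slope`, `intercept`, `p_slope`, `slope_se`, `tau`,
#'   `n`.
#' @export
quantile_model <- function(records, tau = 0.85, n_boot = 200L, seed = 1L) {
  r <- as.data.frame(records)
  ok <- is.finite(r$ltdd_5yr) & is.finite(r$rr) & r$rr > 0
  r <- r[ok, , drop = FALSE]
  if (nrow(r) < 10L)
    stop("need at least 10 records with finite LTDD", call. = FALSE)
  x <- r$ltdd_5yr
  y <- log10(r$rr)
  fit <- fit_quantile_line(x, y, tau)
  set.seed(seed)
  bs <- replicate(n_boot, {
    idx <- sample.int(length(x), replace = TRUE)
    tryCatch(fit_quantile_line(x[idx], y[idx], tau,
                               n_polish = 20L)$coefficients["b"],
             error = function(e) NA_real_)
  })
  se <- stats::sd(bs, na.rm = TRUE)
  tval <- fit$coefficients["b"] / se
  p <- 2 * stats::pt(abs(tval), df = length(x) - 2, lower.tail = FALSE)
  list(slope = unname(fit$coefficients["b"]),
       intercept = unname(fit$coefficients["a"]),
       p_slope = unname(p), slope_se = unname(se), tau = tau, n = length(x))
}

#' Predict the top-resistance map from the quantile model
#'
#' Evaluates `intercept + slope * LTDD` per grid cell (the tau-quantile of
#' log10 RR), zeroes cells whose host presence probability is below the
#' threshold, and excludes the zeroed cells from the output.
#'
#' @param qm A fitted [quantile_model()] (list with `slope`, `intercept`).
#' @param ltdd_grid Numeric matrix of per-cell LTDD.
#' @param host_mask Numeric matrix of host presence probabilities, same
#'   dimensions.
#' @param lats,lons Cell-centre coordinates.
#' @param host_min Host presence threshold (default 0.3).
#' @return Data frame `lat`, `lon`, `log10_rr` over the retained cells.
#' @export
predict_resistance_map <- function(qm, ltdd_grid, host_mask, lats, lons,
                                   host_min = 0.3) {
  ltdd_grid <- as.matrix(ltdd_grid); host_mask <- as.matrix(host_mask)
  if (!identical(dim(ltdd_grid), dim(host_mask)))
    stop("grid geometries do not match", call. = FALSE)
  vals <- qm$intercept + qm$slope * ltdd_grid
  vals[host_mask < host_min] <- 0
  df <- expand.grid(lat = lats, lon = lons, KEEP.OUT.ATTRS = FALSE)
  df$log10_rr <- as.vector(vals)
  df[df$log10_rr != 0, , drop = FALSE]
}

#' Publication-bias check for the meta-analysis
#'
#' Kendall rank correlation between the effect size (logRR) and the bioassay
#' study size (field-population sample size), with the funnel-plot table.
#'
#' @param records Data frame with `log_rr` (or `rr`) and `n_field`.
#' @return List with `kendall_tau`, `p`, and `funnel` (data frame `log_rr`,
#'   `n`). With fewer than 10 usable records or all-tied inputs, `tau` is
#'   `NA` with a message.
#' @export
publication_bias <- function(records) {
  r <- as.data.frame(records)
  if (!"log_rr" %in% names(r)) r$log_rr <- log(r$rr)
  ok <- is.finite(r$log_rr) & is.finite(r$n_field)
  r <- r[ok, , drop = FALSE]
  if (nrow(r) < 10L)
    stop("need at least 10 records with sample sizes", call. = FALSE)
  funnel <- data.frame(log_rr = r$log_rr, n = r$n_field)
  if (length(unique(r$log_rr)) == 1L || length(unique(r$n_field)) == 1L) {
    message("Kendall tau undefined: an input is constant")
    return(list(kendall_tau = NA_real_, p = NA_real_, funnel = funnel))
  }
  ct <- suppressWarnings(
    stats::cor.test(r$log_rr, r$n_field, method = "kendall"))
  list(kendall_tau = unname(ct$estimate), p = ct$p.value, funnel = funnel)
}

#' Read / write resistance records
#'
#' CSV with columns `pesticide`, `moa_group`, `latitude`, `longitude`,
#' `year`, `lc50_field`, `ci_field_lo`, `ci_field_hi`, `n_field`,
#' `lc50_susceptible`, `ci_sus_lo`, `ci_sus_hi`, `n_susceptible`, `rr`;
#' missing values as empty fields.
#'
#' @param path File path.
#' @export
read_resistance_records <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_resistance_records
#' @param records Data frame of records.
#' @export
write_resistance_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}
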