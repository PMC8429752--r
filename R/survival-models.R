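#' Candidate winter-survival model specification
#'
#' The model family crosses three thermal predictors with three functional
#' forms. Predictors: `LTDD` (low-temperature degree-days), `MinDTmean`
#' (lowest daily mean temperature of the exposure window) and `DTmean_days`
#' (mean temperature of the window paired with exposure duration, two
#' covariates). Forms, with S the survival proportion and X the predictor:
#' linear `S = a + b*X`; exponential `S = a*exp(b*X)`; sigmoid
#' `S = a / (1 + exp(-(X - c)/d))`. For `DTmean_days` the single term `b*X`
#' (or `(X - c)/d`'s numerator) is replaced by the additive pair
#' `b1*DTmean + b2*days` (the sigmoid scale is absorbed into b1, b2).
#'
#' @param predictor One of `"LTDD"`, `"MinDTmean"`, `"DTmean_days"`.
#' @param form One of `"linear"`, `"exponential"`, `"sigmoid"`.
#' @return Object of class `model_spec`.
#' @export
survival_spec <- function(predictor = c("LTDD", "MinDTmean", "DTmean_days"),
                          form = c("linear", "exponential", "sigmoid")) {
  predictor <- match.arg(predictor)
  form <- match.arg(form)
  structure(list(predictor = predictor, form = form), class = "model_spec")
}

#' All nine candidate specifications
#' @return List of nine `model_spec` objects (3 predictors x 3 forms).
#' @export
all_survival_specs <- function() {
  out <- list()
  for (p in c("LTDD", "MinDTmean", "DTmean_days"))
    for (f in c("linear", "exponential", "sigmoid"))
      out[[paste(p, f, sep = ".")]] <- survival_spec(p, f)
  out
}

#' @export
format.model_spec <- function(x, ...) paste0(x$form, "(", x$predictor, ")")

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", format(x), "\n"); invisible(x)
}

# number of free coefficients of a spec
.n_coef <- function(spec) {
  base <- switch(spec$form, linear = 2L, exponential = 2L, sigmoid = 3L)
  if (spec$predictor == "DTmean_days") base + 1L else base
}

# design columns required by a spec
.spec_vars <- function(spec) {
  if (spec$predictor == "DTmean_days") c("DTmean", "exposure_days")
  else spec$predictor
}

# evaluate a spec's mean function (unclipped) at coefficient vector `cf`
# over a data frame holding the predictor columns
.spec_mean <- function(spec, cf, data) {
  if (spec$predictor == "DTmean_days") {
    eta <- cf[["b1"]] * data$DTmean + cf[["b2"]] * data$exposure_days
    switch(spec$form,
           linear      = cf[["a"]] + eta,
           exponential = cf[["a"]] * exp(eta),
           sigmoid     = cf[["a"]] / (1 + exp(-(eta - cf[["c"]]))))
  } else {
    x <- data[[spec$predictor]]
    switch(spec$form,
           linear      = cf[["a"]] + cf[["b"]] * x,
           exponential = cf[["a"]] * exp(cf[["b"]] * x),
           sigmoid     = cf[["a"]] / (1 + exp(-(x - cf[["c"]]) / cf[["d"]])))
  }
}

#' Least-squares AIC
#'
#' AIC for a least-squares fit: `n*log(RSS/n) + 2k`, with `k` the number of
#' free mean-function coefficients. The additive constant from the error
#' variance is the same for all models at a given `n` and is omitted; only
#' AIC differences matter for ranking. A perfect fit (RSS = 0) returns
#' `-Inf` as a sentinel.
#'
#' @param residual_ss Residual sum of squares (>= 0).
#' @param n_obs Number of observations.
#' @param k_coefficients Number of fitted coefficients.
#' @return AIC value (possibly `-Inf`).
#' @export
aic_ls <- function(residual_ss, n_obs, k_coefficients) {
  stopifnot(residual_ss >= 0, n_obs > k_coefficients)
  if (residual_ss == 0) return(-Inf)
  n_obs * log(residual_ss / n_obs) + 2 * k_coefficients
}

# multi-start coarse grids of initial values, per spec, given data ranges
.start_grid <- function(spec, data, y, n_starts = 5L, seed = 1L) {
  a0 <- max(min(max(y), 1), 0.05)
  if (spec$predictor == "DTmean_days") {
    xr1 <- range(data$DTmean); xr2 <- range(data$exposure_days)
    s1 <- 1 / max(diff(xr1), 1); s2 <- 1 / max(diff(xr2), 1)
    base <- switch(spec$form,
      linear      = list(a = c(a0, 0.5), b1 = c(0, s1, -s1), b2 = c(0, -s2)),
      exponential = list(a = c(a0, 0.5), b1 = c(0, s1, -s1), b2 = c(0, -s2)),
      sigmoid     = list(a = c(a0, 0.5), b1 = c(s1, -s1), b2 = c(s2, -s2),
                         c = c(0, 1)))
  } else {
    xr <- range(data[[spec$predictor]])
    sc <- max(diff(xr), 1)
    base <- switch(spec$form,
      linear      = list(a = c(a0, 0.5), b = c(0, 1 / sc, -1 / sc)),
      exponential = list(a = c(a0, 0.5), b = c(-1 / sc, -3 / sc, 1 / sc)),
      sigmoid     = list(a = c(a0, 0.5), c = c(mean(xr), xr[1], xr[2]),
                         d = c(sc / 4, -sc / 4, sc / 10)))
  }
  grid <- expand.grid(base, KEEP.OUT.ATTRS = FALSE)
  # deterministic spread over the grid; fitting must not touch the RNG so
  # that callers embedding fits in simulations keep their own streams
  keep <- unique(round(seq(1, nrow(grid), length.out = n_starts)))
  grid[keep, , drop = FALSE]
}

#' Fit one candidate winter-survival model
#'
#' Least-squares fit of observed survival proportions on the spec's thermal
#' predictor(s). Linear forms are fitted by ordinary least squares; the
#' exponential and sigmoid forms by Levenberg-Marquardt nonlinear least
#' squares with a multi-start grid of initial values (fixed seed) to avoid
#' local minima. Fits are on raw proportions, matching the source analysis;
#' predictions from the fitted object are clipped to [0, 1].
#'
#' @param observations Data frame with a `survival` column (proportion in
#'   [0,1]), or columns `n_exposed`/`n_survived` from which it is computed,
#'   plus the predictor columns `LTDD`, `MinDTmean`, `DTmean`,
#'   `exposure_days` as required by `spec`.
#' @param spec A [survival_spec()].
#' @param seed Integer seed controlling the multi-start order (determinism).
#' @param n_starts Number of multi-start initial values for nonlinear fits.
#' @param start Optional named coefficient vector used as the only start
#'   (warm start, e.g. for bootstrap refits); overrides the grid.
#' @return Object of class `ows_fit`: list with `spec`, `coefficients`,
#'   `r2`, `aic`, `n_obs`, `residual_ss`, `fitted`, `data`, `converged`,
#'   `vcov` (nonlinear fits).
#' @seealso [compare_models()], [predict.ows_fit()], [validate_field()]
#' @examples
#' set.seed(1)
#' d <- data.frame(LTDD = seq(0, 500, by = 50))
#' d$survival <- 0.9 * exp(-0.005 * d$LTDD)
#' f <- fit_survival_model(d, survival_spec("LTDD", "exponential"))
#' coef(f)
#' @export
fit_survival_model <- function(observations, spec, seed = 1L,
                               n_starts = 5L, start = NULL) {
  obs <- as.data.frame(observations)
  if (!"survival" %in% names(obs)) {
    if (!all(c("n_exposed", "n_survived") %in% names(obs)))
      stop("need survival or n_exposed/n_survived columns", call. = FALSE)
    obs$survival <- obs$n_survived / obs$n_exposed
  }
  vars <- .spec_vars(spec)
  miss <- setdiff(vars, names(obs))
  if (length(miss))
    stop("missing predictor column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(obs$survival)) ||
      any(!vapply(vars, function(v) all(is.finite(obs[[v]])), logical(1))))
    stop("non-finite survival or predictor values", call. = FALSE)
  k <- .n_coef(spec)
  n <- nrow(obs)
  if (n < k + 3L)
    stop("need at least 3 more observations than coefficients", call. = FALSE)
  # order invariance: fit on a canonical ordering of the observations
  ord <- do.call(order, c(unname(obs[vars]), list(obs$survival)))
  obs_f <- obs[ord, , drop = FALSE]
  y <- obs_f$survival

  cf <- NULL; vc <- NULL; converged <- TRUE
  if (spec$form == "linear") {
    fml <- if (spec$predictor == "DTmean_days")
      survival ~ DTmean + exposure_days else
      stats::reformulate(spec$predictor, "survival")
    lf <- stats::lm(fml, data = obs_f)
    b <- stats::coef(lf)
    cf <- if (spec$predictor == "DTmean_days")
      c(a = unname(b[1]), b1 = unname(b[2]), b2 = unname(b[3])) else
      c(a = unname(b[1]), b = unname(b[2]))
    vc <- stats::vcov(lf)
  } else {
    fml <- if (spec$predictor == "DTmean_days") {
      switch(spec$form,
        exponential = survival ~ a * exp(b1 * DTmean + b2 * exposure_days),
        sigmoid = survival ~
          a / (1 + exp(-(b1 * DTmean + b2 * exposure_days - c))))
    } else {
      x <- as.name(spec$predictor)
      switch(spec$form,
        exponential = stats::as.formula(
          substitute(survival ~ a * exp(b * X), list(X = x))),
        sigmoid = stats::as.formula(
          substitute(survival ~ a / (1 + exp(-(X - c) / d)), list(X = x))))
    }
    starts <- if (!is.null(start))
      as.data.frame(as.list(start)) else
      .start_grid(spec, obs_f, y, n_starts, seed)
    # the plateau parameter a is the asymptotic survival proportion of the
    # nonlinear forms, so it is constrained to (0, 1]; remaining
    # coefficients are free
    lower <- rep(-Inf, ncol(starts)); upper <- rep(Inf, ncol(starts))
    names(lower) <- names(upper) <- names(starts)
    lower["a"] <- 1e-8; upper["a"] <- 1
    best <- NULL; best_rss <- Inf; diag_msgs <- character()
    for (i in seq_len(nrow(starts))) {
      st <- as.list(starts[i, , drop = FALSE])
      fit <- tryCatch(
        minpack.lm::nlsLM(fml, data = obs_f, start = st,
                          lower = lower, upper = upper,
                          control = minpack.lm::nls.lm.control(
                            maxiter = 200, ftol = 1e-10)),
        error = function(e) e)
      if (inherits(fit, "error")) {
        diag_msgs <- c(diag_msgs, conditionMessage(fit)); next
      }
      rss <- sum(stats::residuals(fit)^2)
      if (rss < best_rss) { best <- fit; best_rss <- rss }
    }
    if (is.null(best)) {
      cond <- structure(
        class = c("ows_fit_failure", "error", "condition"),
        list(message = paste0("all ", nrow(starts),
                              " starts failed for ", format(spec)),
             call = sys.call(-1), diagnostics = diag_msgs))
      stop(cond)
    }
    cf <- stats::coef(best)
    vc <- tryCatch(stats::vcov(best), error = function(e) NULL)
    converged <- best$convInfo$isConv %||% TRUE
  }

  fitted_raw <- .spec_mean(spec, as.list(cf), obs_f)
  rss <- sum((y - fitted_raw)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  structure(list(spec = spec, coefficients = cf, r2 = r2,
                 aic = aic_ls(rss, n, k), n_obs = n, residual_ss = rss,
                 fitted = pmin(1, pmax(0, fitted_raw)), data = obs_f,
                 converged = converged, vcov = vc, k = k),
            class = "ows_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ows_fit <- function(x, digits = 4, ...) {
  cat("Winter-survival model:", format(x$spec), "\n")
  cat("Coefficients:\n")
  print(round(x$coefficients, digits))
  cat(sprintf("n = %d, R2 = %.3f, AIC = %.2f\n", x$n_obs, x$r2, x$aic))
  invisible(x)
}

#' @export
summary.ows_fit <- function(object, ...) {
  se <- if (!is.null(object$vcov)) sqrt(diag(object$vcov)) else
    rep(NA_real_, length(object$coefficients))
  out <- list(spec = object$spec,
              coef_table = cbind(Estimate = object$coefficients,
                                 `Std. Error` = se),
              r2 = object$r2, aic = object$aic, n_obs = object$n_obs,
              residual_ss = object$residual_ss)
  class(out) <- "summary.ows_fit"
  out
}

#' @export
print.summary.ows_fit <- function(x, ...) {
  cat("Winter-survival model:", format(x$spec), "\n\n")
  stats::printCoefmat(x$coef_table, has.Pvalue = FALSE)
  cat(sprintf("\nn = %d, RSS = %.4g, R2 = %.3f, AIC = %.2f\n",
              x$n_obs, x$residual_ss, x$r2, x$aic))
  invisible(x)
}

#' @export
coef.ows_fit <- function(object, ...) object$coefficients

#' Confidence intervals for survival-model coefficients
#'
#' `method = "boot"` (default) resamples observations with replacement,
#' refits, and reports percentile intervals; the case bootstrap respects the
#' binomial (variance varies with the mean) error structure of survival
#' proportions, which the least-squares Wald intervals (`method = "wald"`)
#' ignore.
#'
#' @param object An `ows_fit` (with training data attached).
#' @param parm Coefficients to report (default all).
#' @param level Confidence level (default 0.95).
#' @param method `"boot"` or `"wald"`.
#' @param n_boot Bootstrap replicates (default 199).
#' @param seed Integer seed for the bootstrap.
#' @param ... Unused.
#' @return Matrix with one row per coefficient, columns lower/upper.
#' @export
confint.ows_fit <- function(object, parm, level = 0.95,
                            method = c("boot", "wald"), n_boot = 199L,
                            seed = 1L, ...) {
  method <- match.arg(method)
  cf <- object$coefficients
  if (missing(parm)) parm <- names(cf)
  alpha <- (1 - level) / 2
  if (method == "wald") {
    if (is.null(object$vcov)) stop("no vcov available", call. = FALSE)
    se <- sqrt(diag(object$vcov))[parm]
    out <- cbind(cf[parm] + stats::qnorm(alpha) * se,
                 cf[parm] + stats::qnorm(1 - alpha) * se)
  } else {
    if (is.null(object$data)) stop("no training data attached", call. = FALSE)
    set.seed(seed)
    n <- nrow(object$data)
    draws <- matrix(NA_real_, n_boot, length(cf),
                    dimnames = list(NULL, names(cf)))
    for (bi in seq_len(n_boot)) {
      idx <- sample.int(n, replace = TRUE)
      ft <- tryCatch(
        fit_survival_model(object$data[idx, , drop = FALSE], object$spec,
                           seed = seed, start = object$coefficients),
        error = function(e) NULL)
      if (!is.null(ft)) draws[bi, ] <- ft$coefficients
    }
    out <- t(apply(draws[, parm, drop = FALSE], 2, stats::quantile,
                   probs = c(alpha, 1 - alpha), na.rm = TRUE))
  }
  colnames(out) <- paste(format(100 * c(alpha, 1 - alpha), trim = TRUE),
                         "%")
  rownames(out) <- parm
  out
}

#' Joint bootstrap confidence region for the fitted coefficients
#'
#' Case-bootstrap analogue of a Wald confidence ellipsoid: resampled refits
#' give a coefficient covariance estimate, and the region's radius is the
#' `level` quantile of the bootstrap Mahalanobis distances, so the region is
#' calibrated without assuming normality or homoscedasticity. Use the
#' returned `contains` predicate to test whether a coefficient vector (e.g.
#' a simulation truth) lies inside.
#'
#' @inheritParams confint.ows_fit
#' @param fit An `ows_fit` with training data attached.
#' @return List with `center`, `cov`, `radius2` (squared Mahalanobis
#'   threshold) and `contains(theta)`.
#' @export
boot_confidence_region <- function(fit, level = 0.95, n_boot = 199L,
                                   seed = 1L) {
  stopifnot(inherits(fit, "ows_fit"), !is.null(fit$data))
  set.seed(seed)
  n <- nrow(fit$data)
  draws <- matrix(NA_real_, n_boot, length(fit$coefficients),
                  dimnames = list(NULL, names(fit$coefficients)))
  for (bi in seq_len(n_boot)) {
    idx <- sample.int(n, replace = TRUE)
    ft <- tryCatch(
      fit_survival_model(fit$data[idx, , drop = FALSE], fit$spec,
                         seed = seed, start = fit$coefficients),
      error = function(e) NULL)
    if (!is.null(ft)) draws[bi, ] <- ft$coefficients
  }
  draws <- draws[stats::complete.cases(draws), , drop = FALSE]
  ctr <- fit$coefficients
  S <- stats::cov(draws)
  Sinv <- solve(S + diag(1e-12, ncol(S)))
  d2 <- mahalanobis(draws, ctr, Sinv, inverted = TRUE)
  r2 <- stats::quantile(d2, level, names = FALSE)
  list(center = ctr, cov = S, radius2 = r2,
       contains = function(theta)
         mahalanobis(rbind(theta), ctr, Sinv, inverted = TRUE) <= r2)
}

#' Predict survival from a fitted model
#'
#' Evaluates the fitted mean function and clips the result to [0, 1].
#' `newdata` may be a data frame carrying the predictor columns, or, for
#' single-predictor specs, a bare numeric vector of predictor values.
#'
#' @param object An `ows_fit`.
#' @param newdata Data frame or numeric vector of predictor values; defaults
#'   to the training data.
#' @param ... Unused.
#' @return Numeric vector of survival proportions in [0, 1].
#' @export
predict.ows_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  if (is.numeric(newdata) && object$spec$predictor != "DTmean_days") {
    nd <- stats::setNames(data.frame(x = as.numeric(newdata)),
                          object$spec$predictor)
  } else {
    nd <- as.data.frame(newdata)
    miss <- setdiff(.spec_vars(object$spec), names(nd))
    if (length(miss))
      stop("newdata lacks predictor column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
  }
  vals <- lapply(.spec_vars(object$spec), function(v) nd[[v]])
  if (any(!vapply(vals, function(v) all(is.finite(v)), logical(1))))
    stop("non-finite predictor values", call. = FALSE)
  pmin(1, pmax(0, .spec_mean(object$spec, as.list(object$coefficients), nd)))
}

#' @export
residuals.ows_fit <- function(object, ...) {
  object$data$survival - object$fitted
}

#' Simulate binomial survival counts from a fitted model
#'
#' Draws `n_survived ~ Binomial(n_exposed, S(predictors))` for each row of
#' `newdata`, with S the clipped fitted survival.
#'
#' @param object An `ows_fit`.
#' @param nsim Number of simulated response sets.
#' @param seed Optional integer seed.
#' @param newdata Data frame with predictor columns and `n_exposed`;
#'   defaults to the training data (requires `n_exposed` there).
#' @param ... Unused.
#' @return Data frame of `nsim` columns of simulated survived counts.
#' @export
simulate.ows_fit <- function(object, nsim = 1, seed = NULL,
                             newdata = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  nd <- if (is.null(newdata)) object$data else as.data.frame(newdata)
  if (!"n_exposed" %in% names(nd))
    stop("newdata needs an n_exposed column", call. = FALSE)
  p <- predict(object, nd)
  out <- as.data.frame(replicate(
    nsim, stats::rbinom(length(p), nd$n_exposed, p)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.ows_fit <- function(x, ...) {
  if (x$spec$predictor == "DTmean_days") {
    plot(x$fitted, x$data$survival, xlab = "fitted survival",
         ylab = "observed survival", ...)
    graphics::abline(0, 1, lty = 2)
  } else {
    v <- x$data[[x$spec$predictor]]
    plot(v, x$data$survival, xlab = x$spec$predictor,
         ylab = "survival", ...)
    xx <- seq(min(v), max(v), length.out = 200)
    graphics::lines(xx, predict(x, xx), col = 2)
  }
  invisible(x)
}

#' Fit and rank the candidate model family
#'
#' Fits every spec in `specs` and returns the family ranked by ascending
#' AIC; ties are broken by higher R-squared, then by fewer coefficients.
#' Specs that fail to fit are kept in the table with NA statistics.
#'
#' @inheritParams fit_survival_model
#' @param specs List of [survival_spec()]s; default all nine.
#' @return Object of class `ows_comparison`: a data frame with columns
#'   `predictor`, `form`, `k`, `r2`, `aic`, `rank`, `converged`, plus the
#'   fitted models in `attr(, "fits")` (in table order).
#' @export
compare_models <- function(observations, specs = all_survival_specs(),
                           seed = 1L) {
  if (inherits(specs, "model_spec")) specs <- list(specs)
  fits <- lapply(specs, function(sp)
    tryCatch(fit_survival_model(observations, sp, seed = seed),
             error = function(e) e))
  ok <- !vapply(fits, inherits, logical(1), "error")
  if (!any(ok)) stop("all model fits failed", call. = FALSE)
  tab <- data.frame(
    predictor = vapply(specs, function(s) s$predictor, character(1)),
    form = vapply(specs, function(s) s$form, character(1)),
    k = vapply(specs, .n_coef, integer(1)),
    r2 = ifelse(ok, vapply(fits, function(f)
      if (inherits(f, "error")) NA_real_ else f$r2, numeric(1)), NA),
    aic = ifelse(ok, vapply(fits, function(f)
      if (inherits(f, "error")) NA_real_ else f$aic, numeric(1)), NA),
    converged = ifelse(ok, vapply(fits, function(f)
      if (inherits(f, "error")) FALSE else isTRUE(f$converged), logical(1)),
      FALSE))
  ord <- order(ifelse(is.na(tab$aic), Inf, tab$aic), -tab$r2, tab$k)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(tab, fits = fits[ord], class = c("ows_comparison", "data.frame"))
}

#' @export
print.ows_comparison <- function(x, digits = 3, ...) {
  cat("Winter-survival model comparison (ascending AIC):\n")
  df <- as.data.frame(x)
  df$r2 <- round(df$r2, digits); df$aic <- round(df$aic, 2)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Extract the best-ranked fitted model from a comparison
#' @param comparison An `ows_comparison`.
#' @return The `ows_fit` ranked first.
#' @export
best_model <- function(comparison) {
  stopifnot(inherits(comparison, "ows_comparison"))
  attr(comparison, "fits")[[1]]
}

#' Validate model predictions against field observations
#'
#' Ordinary least-squares regression of observed field survival on the
#' model's predictions (computed from climate predictors independent of the
#' field outcomes). Returns the regression slope, intercept, R-squared and
#' the prediction bias |slope - 1|. Field observations from sites so warm
#' that the exposure window accumulates no cold (LTDD = 0) can be excluded,
#' mirroring the exclusion of warm sites where year-round breeding makes
#' winter survival unidentifiable.
#'
#' @param model An `ows_fit`.
#' @param field_observations Data frame with `survival` (or
#'   `n_exposed`/`n_survived`) plus the model's predictor columns; an `LTDD`
#'   column and a `setting` column are consulted for the warm-site
#'   exclusion.
#' @param exclude_zero_ltdd Drop field records with `LTDD == 0`
#'   (default TRUE).
#' @return Object of class `ows_validation`: list with `slope`, `intercept`,
#'   `r2`, `n`, `bias`.
#' @export
validate_field <- function(model, field_observations,
                           exclude_zero_ltdd = TRUE) {
  obs <- as.data.frame(field_observations)
  if (!"survival" %in% names(obs))
    obs$survival <- obs$n_survived / obs$n_exposed
  if (exclude_zero_ltdd && "LTDD" %in% names(obs)) {
    is_field <- if ("setting" %in% names(obs))
      obs$setting %in% c("field_plant", "field_jar") else TRUE
    obs <- obs[!(is_field & obs$LTDD == 0), , drop = FALSE]
  }
  if (nrow(obs) < 3L)
    stop("need at least 3 field observations", call. = FALSE)
  pred <- predict(model, obs)
  lf <- stats::lm(obs$survival ~ pred)
  sm <- summary(lf)
  structure(list(slope = unname(stats::coef(lf)[2]),
                 intercept = unname(stats::coef(lf)[1]),
                 r2 = sm$r.squared, n = nrow(obs),
                 bias = abs(unname(stats::coef(lf)[2]) - 1),
                 slope_se = sm$coefficients[2, 2]),
            class = "ows_validation")
}

#' @export
print.ows_validation <- function(x, ...) {
  cat(sprintf(
    "Field validation (n = %d): slope %.3f, intercept %.3f, R2 %.3f, bias %.3f\n",
    x$n, x$slope, x$intercept, x$r2, x$bias))
  invisible(x)
}

#' Serialize / restore a fitted survival model
#'
#' Writes a self-describing plain-text (JSON) representation of the spec,
#' coefficients and fit statistics so a fitted model can be reused by the
#' range-mapping stage without re-fitting.
#'
#' @param model An `ows_fit`.
#' @param path File path.
#' @return `read_survival_model` returns an `ows_fit` (without training
#'   data; prediction works, refitting does not).
#' @export
write_survival_model <- function(model, path) {
  obj <- list(predictor = model$spec$predictor, form = model$spec$form,
              coefficients = as.list(model$coefficients),
              r2 = model$r2, aic = model$aic, n_obs = model$n_obs,
              residual_ss = model$residual_ss)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_survival_model
#' @export
read_survival_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(spec = survival_spec(obj$predictor, obj$form),
                 coefficients = unlist(obj$coefficients),
                 r2 = obj$r2, aic = obj$aic, n_obs = obj$n_obs,
                 residual_ss = obj$residual_ss, fitted = NULL, data = NULL,
                 converged = TRUE, vcov = NULL,
                 k = length(obj$coefficients)),
            class = "ows_fit")
}
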