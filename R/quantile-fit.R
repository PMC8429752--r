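# Linear quantile regression by direct pinball-loss minimization.
#
# The tau-quantile line minimizes sum_i rho_tau(y_i - a - b*x_i) with
# rho_tau(r) = r*(tau - 1{r<0}). An optimum always lies at a "vertex":
# a line passing through (at least) two data points. The fitter runs an
# iteratively reweighted least-squares continuation (a smoothed surrogate)
# to locate the neighbourhood of the optimum, then polishes exactly by
# enumerating candidate vertex lines through pairs of near-zero-residual
# points and keeping the lowest exact pinball loss.

.pinball_loss <- function(r, tau) sum(r * (tau - (r < 0)))

# exact line through two points (returns NULL for vertical pairs)
.pair_line <- function(x1, y1, x2, y2) {
  if (x1 == x2) return(NULL)
  b <- (y2 - y1) / (x2 - x1)
  c(a = y1 - b * x1, b = b)
}

#' Fit a linear quantile regression by pinball-loss minimization
#'
#' Estimates the straight line whose residuals minimize the tau-quantile
#' check (pinball) loss. Smooth iteratively-reweighted least squares with a
#' shrinking smoothing parameter locates the solution region; an exact
#' vertex polish (enumeration of lines through pairs of low-residual data
#' points, scored by the exact loss over all observations) then returns the
#' optimal vertex line.
#'
#' @param x,y Numeric vectors (equal length, finite).
#' @param tau Quantile level in (0, 1).
#' @param n_polish Number of smallest-|residual| points whose pairs are
#'   enumerated in the polish step (default 40, capped at n).
#' @return List with `coefficients` (named `a` intercept, `b` slope),
#'   `loss` (pinball loss at the optimum), `tau`, `n`.
#' @export
fit_quantile_line <- function(x, y, tau = 0.85, n_polish = 40L) {
  stopifnot(length(x) == length(y), length(x) >= 3,
            all(is.finite(x)), all(is.finite(y)), tau > 0, tau < 1)
  n <- length(x)
  if (stats::var(x) == 0) stop("degenerate design: constant x", call. = FALSE)

  beta <- stats::coef(stats::lm(y ~ x))
  for (eps in c(1, 0.1, 0.01, 1e-3, 1e-4, 1e-5)) {
    for (it in 1:30) {
      r <- y - beta[1] - beta[2] * x
      w <- ifelse(r >= 0, tau, 1 - tau) / pmax(abs(r), eps)
      fit <- stats::lm.wfit(cbind(1, x), y, w)
      new_beta <- fit$coefficients
      if (max(abs(new_beta - beta)) < 1e-12) { beta <- new_beta; break }
      beta <- new_beta
    }
  }

  # exact vertex polish around the IRLS solution
  r <- y - beta[1] - beta[2] * x
  cand <- order(abs(r))[seq_len(min(n_polish, n))]
  best <- c(a = unname(beta[1]), b = unname(beta[2]))
  best_loss <- .pinball_loss(r, tau)
  for (ii in seq_along(cand)) {
    for (jj in seq_len(ii - 1L)) {
      i <- cand[ii]; j <- cand[jj]
      ln <- .pair_line(x[i], y[i], x[j], y[j])
      if (is.null(ln)) next
      loss <- .pinball_loss(y - ln["a"] - ln["b"] * x, tau)
      if (loss < best_loss - 1e-12) { best <- ln; best_loss <- loss }
    }
  }
  list(coefficients = best, loss = best_loss, tau = tau, n = n)
}

# Exact brute-force quantile line: enumerate every pair of points. O(n^3);
# intended as an independent oracle at small n.
.quantile_line_bruteforce <- function(x, y, tau) {
  n <- length(x)
  best <- NULL; best_loss <- Inf
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      ln <- .pair_line(x[i], y[i], x[j], y[j])
      if (is.null(ln)) next
      loss <- .pinball_loss(y - ln["a"] - ln["b"] * x, tau)
      if (loss < best_loss) { best <- ln; best_loss <- loss }
    }
  }
  list(coefficients = best, loss = best_loss, tau = tau, n = n)
}
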