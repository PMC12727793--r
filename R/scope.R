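#' SCOPE calibration configuration
#'
#' Settings for output-stratified inductive conformal calibration: the target
#' calibration density per stratum, the confidence-level grid materialised at
#' fit time, and the quantile convention.
#'
#' @param density target number of calibration points per stratum, D
#'   (default 1000); the stratum count is `ceiling(N / D)`.
#' @param levels confidence levels materialised in the fitted table; defaults
#'   to the Gaussian 1/2/3-sigma levels (0.6827, 0.9545, 0.9973) plus the
#'   1--99 percent grid used for coverage curves. Other levels are computed
#'   on demand from the stored scores.
#' @param convention `"conformal"` (default): the finite-sample order
#'   statistic `ceiling(level * (m + 1))`, clamped to m, which preserves the
#'   marginal coverage guarantee; `"empirical"`: the plain empirical quantile
#'   `ceiling(level * m)`.
#' @return object of class `scope_config`.
#' @export
scope_config <- function(density = 1000,
                         levels = sort(unique(c(0.6827, 0.9545, 0.9973,
                                                (1:99) / 100))),
                         convention = c("conformal", "empirical")) {
  stop_if_not(is_count(density), "density must be a positive integer")
  stop_if_not(all(levels > 0 & levels < 1), "levels must lie in (0, 1)")
  structure(list(density = as.integer(density), levels = levels,
                 convention = match.arg(convention)),
            class = "scope_config")
}

#' Number of strata for a calibration set
#'
#' `ceiling(N / D)`: with the default density D = 1000, a calibration set of
#' 23,862 points yields 24 strata.
#'
#' @param n_cal calibration set size N.
#' @param density target points per stratum D.
#' @return integer stratum count, at least 1.
#' @export
num_strata <- function(n_cal, density) {
  stop_if_not(is_count(n_cal) && is_count(density),
              "N and D must be positive integers")
  as.integer(ceiling(n_cal / density))
}

#' Nonconformity score
#'
#' The absolute residual \eqn{\epsilon = |\hat y - y|}.
#'
#' @param y_hat predicted values.
#' @param y observed values.
#' @return nonnegative numeric vector.
#' @export
nonconformity <- function(y_hat, y) {
  stop_if_not(all(is.finite(y_hat)) && all(is.finite(y)),
              "inputs must be finite")
  abs(y_hat - y)
}

#' Per-stratum conformal quantile
#'
#' For m sorted scores and confidence level gamma, the default conformal
#' convention returns the k-th smallest score with
#' `k = ceiling(gamma * (m + 1))` clamped to m; the empirical convention uses
#' `k = ceiling(gamma * m)`.
#'
#' @param scores sorted (or unsorted; sorted internally) nonconformity
#'   scores, length >= 1.
#' @param level confidence level in (0, 1); vectorised.
#' @param convention `"conformal"` or `"empirical"`.
#' @return quantile(s) Q, same length as `level`.
#' @export
stratum_quantile <- function(scores, level,
                             convention = c("conformal", "empirical")) {
  stop_if_not(length(scores) >= 1, "scores must be non-empty")
  stop_if_not(all(level > 0 & level < 1), "level must lie in (0, 1)")
  convention <- match.arg(convention)
  s <- sort(scores)
  m <- length(s)
  k <- if (convention == "conformal") ceiling(level * (m + 1))
       else ceiling(level * m)
  s[pmin(pmax(k, 1L), m)]
}

#' Fit a SCOPE calibrator
#'
#' Stratifies the calibration pairs into equal-frequency bins of the
#' predicted value, computes nonconformity scores within each stratum, and
#' materialises per-stratum quantiles for the configured level grid. The
#' interior edges are the i/n order-statistic quantiles of the calibration
#' predictions; bins are closed on the left and open on the right, with the
#' last bin closed above and out-of-range predictions clamped to the extreme
#' strata. If N < 2D a single stratum is used (plain inductive conformal
#' prediction) with a warning.
#'
#' @param y_hat_cal calibration predictions.
#' @param y_cal calibration observations (same length).
#' @param config a [scope_config()].
#' @return object of class `scope`: calibration size `n_cal`, stratum count
#'   `n_strata`, interior `edges`, per-stratum member `counts`, sorted
#'   `scores` per stratum, `quantiles` matrix (stratum x level), residual
#'   `sigma` per stratum, and the `config`.
#' @seealso [predict_interval()], [assign_stratum()], [scope_to_json()]
#' @export
fit_scope <- function(y_hat_cal, y_cal, config = scope_config()) {
  stop_if_not(length(y_hat_cal) == length(y_cal),
              "calibration arrays must be paired")
  stop_if_not(length(y_cal) >= 1, "calibration set is empty")
  stop_if_not(all(is.finite(y_hat_cal)) && all(is.finite(y_cal)),
              "calibration values must be finite")
  N <- length(y_cal)
  n <- num_strata(N, config$density)
  if (N < 2 * config$density && n > 1) n <- 1L
  if (N < 2 * config$density && num_strata(N, config$density) > 1)
    warning("calibration set smaller than 2 x density; using one stratum")
  edges <- if (n > 1) {
    sort(y_hat_cal)[ceiling(N * seq_len(n - 1) / n)]
  } else numeric()
  idx <- assign_bins(y_hat_cal, edges)
  eps <- nonconformity(y_hat_cal, y_cal)
  scores <- lapply(seq_len(n), function(i) sort(eps[idx == i]))
  counts <- vapply(scores, length, 0L)
  stop_if_not(all(counts >= 1),
              "empty stratum produced; lower the density or check for ties")
  quantiles <- t(vapply(scores, function(s)
    stratum_quantile(s, config$levels, config$convention),
    numeric(length(config$levels))))
  colnames(quantiles) <- format_level(config$levels)
  sigma <- vapply(seq_len(n), function(i) {
    r <- y_hat_cal[idx == i] - y_cal[idx == i]
    sqrt(mean(r^2))
  }, 0)
  structure(list(n_cal = N, n_strata = n, edges = edges, counts = counts,
                 scores = scores, quantiles = quantiles, sigma = sigma,
                 config = config),
            class = "scope")
}

format_level <- function(level) sprintf("%.6f", level)

# half-open bins [e_{i-1}, e_i); last bin closed above; clamped at both ends
assign_bins <- function(x, edges) {
  if (length(edges) == 0) return(rep(1L, length(x)))
  findInterval(x, edges, left.open = FALSE) + 1L
}

#' Assign new predictions to strata
#'
#' @param table a fitted [fit_scope()] object.
#' @param y_hat_new numeric predictions (finite).
#' @return integer stratum indices in 1..n_strata.
#' @export
assign_stratum <- function(table, y_hat_new) {
  stop_if_not(inherits(table, "scope"), "table must come from fit_scope()")
  stop_if_not(all(is.finite(y_hat_new)), "predictions must be finite")
  assign_bins(y_hat_new, table$edges)
}

scope_quantile_at <- function(table, level) {
  key <- format_level(level)
  if (key %in% colnames(table$quantiles)) return(table$quantiles[, key])
  vapply(table$scores, function(s)
    stratum_quantile(s, level, table$config$convention), 0)
}

#' Conformal prediction intervals from a SCOPE table
#'
#' Builds symmetric intervals `[y_hat - Q, y_hat + Q]` where Q is the fitted
#' nonconformity quantile of the stratum the prediction falls in. Under
#' exchangeability of the calibration and test data, the observed value lies
#' inside the interval with at least the nominal probability.
#'
#' @param table a fitted [fit_scope()] object.
#' @param y_hat_new numeric predictions.
#' @param level nominal confidence level in (0, 1); levels outside the fitted
#'   grid are recomputed on demand from the stored scores.
#' @return data frame of class `prediction_interval` with columns
#'   `y_hat, lower, upper, level, stratum`.
#' @export
predict_interval <- function(table, y_hat_new, level = 0.9545) {
  stop_if_not(inherits(table, "scope"), "table must come from fit_scope()")
  stop_if_not(length(level) == 1 && level > 0 && level < 1,
              "level must be a single value in (0, 1)")
  stratum <- assign_stratum(table, y_hat_new)
  Q <- scope_quantile_at(table, level)[stratum]
  out <- data.frame(y_hat = y_hat_new, lower = y_hat_new - Q,
                    upper = y_hat_new + Q, level = level, stratum = stratum)
  class(out) <- c("prediction_interval", class(out))
  out
}

#' @export
predict.scope <- function(object, y_hat_new, level = 0.9545, ...) {
  predict_interval(object, y_hat_new, level)
}

#' @export
print.scope <- function(x, ...) {
  cat(sprintf("SCOPE calibrator: %d calibration points in %d strat%s\n",
              x$n_cal, x$n_strata, if (x$n_strata == 1) "um" else "a"))
  cat(sprintf("  convention: %s quantile, density target %d\n",
              x$config$convention, x$config$density))
  invisible(x)
}

#' @export
summary.scope <- function(object, levels = c(0.6827, 0.9545, 0.9973), ...) {
  lo <- c(-Inf, object$edges)
  hi <- c(object$edges, Inf)
  out <- data.frame(stratum = seq_len(object$n_strata), lower_edge = lo,
                    upper_edge = hi, n = object$counts,
                    sigma = object$sigma)
  for (lv in levels)
    out[[paste0("Q_", format(lv))]] <- scope_quantile_at(object, lv)
  out
}

#' Plot per-stratum interval half-widths
#'
#' Shows the fitted nonconformity quantiles per stratum at the requested
#' levels, with dashed 1/2/3-sigma reference lines from the per-stratum
#' residual standard deviation.
#'
#' @param x a fitted `scope` object.
#' @param levels confidence levels to draw.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.scope <- function(x, levels = c(0.6827, 0.9545, 0.9973), ...) {
  qs <- vapply(levels, function(lv) scope_quantile_at(x, lv),
               numeric(x$n_strata))
  mids <- seq_len(x$n_strata)
  graphics::matplot(mids, qs, type = "b", pch = 16, lty = 1,
                    xlab = "stratum (increasing predicted CBT)",
                    ylab = "interval half-width Q (degC)", ...)
  for (z in 1:3)
    graphics::lines(mids, z * x$sigma, lty = 2, col = "grey50")
  graphics::legend("topleft", legend = c(sprintf("%.2f%%", 100 * levels),
                                         "1/2/3 sigma"),
                   lty = c(rep(1, length(levels)), 2), bty = "n",
                   col = c(seq_along(levels), "grey50"))
  invisible(x)
}
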