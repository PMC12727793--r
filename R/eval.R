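#' Root mean squared error
#'
#' @param predictions,observations paired numeric vectors.
#' @return RMSE in the units of the inputs (degC here).
#' @export
rmse <- function(predictions, observations) {
  stop_if_not(length(predictions) == length(observations),
              "inputs must be paired")
  stop_if_not(length(predictions) > 0, "inputs are empty")
  sqrt(mean((predictions - observations)^2))
}

#' Per subject-session RMSE table
#'
#' Computes RMSE separately for every subject-session, including only
#' sessions with at least `min_points` valid timepoints (a timepoint is valid
#' when both the prediction and the observation are present). Excluded
#' sessions are listed, with the reason, in the `excluded` attribute.
#'
#' @param predictions numeric predictions.
#' @param observations numeric observations.
#' @param provenance data frame with `subject_id` and `session_id` aligned
#'   with the predictions.
#' @param min_points inclusion threshold (default 10).
#' @param model_tag label recorded in the output (default `"model"`).
#' @return data frame `subject_id, session_id, n, rmse, model`; attribute
#'   `excluded` lists dropped sessions.
#' @export
session_rmse_table <- function(predictions, observations, provenance,
                               min_points = 10, model_tag = "model") {
  stop_if_not(length(predictions) == length(observations) &&
                length(predictions) == nrow(provenance),
              "predictions, observations and provenance must be aligned")
  ok <- is.finite(predictions) & is.finite(observations)
  key <- paste(provenance$subject_id, provenance$session_id, sep = "\r")
  rows <- list(); dropped <- list()
  for (kk in unique(key)) {
    sel <- key == kk & ok
    n <- sum(sel)
    parts <- strsplit(kk, "\r")[[1]]
    if (n >= min_points) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = parts[1], session_id = parts[2], n = n,
        rmse = rmse(predictions[sel], observations[sel]),
        model = model_tag, stringsAsFactors = FALSE)
    } else {
      dropped[[length(dropped) + 1L]] <- data.frame(
        subject_id = parts[1], session_id = parts[2], n = n,
        reason = sprintf("fewer than %d valid timepoints", min_points),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject_id = character(), session_id = character(),
               n = integer(), rmse = numeric(), model = character())
  attr(out, "excluded") <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(subject_id = character(), session_id = character(),
               n = integer(), reason = character())
  out
}

#' Empirical interval coverage
#'
#' The percentage of observations falling inside their prediction interval,
#' bounds inclusive.
#'
#' @param intervals data frame with `lower` and `upper` columns (e.g. from
#'   [predict_interval()] or [ekf_intervals()]).
#' @param observations paired numeric observations.
#' @return coverage in percent (0--100).
#' @export
coverage <- function(intervals, observations) {
  stop_if_not(nrow(intervals) == length(observations),
              "intervals and observations must be paired")
  stop_if_not(length(observations) > 0, "inputs are empty")
  100 * mean(observations >= intervals$lower &
               observations <= intervals$upper)
}

#' Empirical coverage curve
#'
#' Evaluates coverage at every level of a confidence grid, given a function
#' that produces intervals at an arbitrary level.
#'
#' @param interval_fun function of one argument (confidence level in (0, 1))
#'   returning an interval data frame with `lower`/`upper` aligned with
#'   `observations`.
#' @param observations numeric observations.
#' @param grid confidence grid in percent (default 1--99).
#' @return data frame of class `coverage_curve` with columns
#'   `level` (percent) and `coverage` (percent).
#' @export
coverage_curve <- function(interval_fun, observations, grid = 1:99) {
  stop_if_not(is.function(interval_fun), "interval_fun must be a function")
  stop_if_not(all(diff(grid) > 0), "grid must be strictly increasing")
  stop_if_not(all(grid > 0 & grid < 100), "grid must lie inside (0, 100)")
  cov <- vapply(grid, function(g)
    coverage(interval_fun(g / 100), observations), 0)
  out <- data.frame(level = grid, coverage = cov)
  class(out) <- c("coverage_curve", class(out))
  out
}

#' Area under the coverage curve
#'
#' Trapezoidal integral of empirical coverage (percent) over nominal
#' confidence (percent) on a grid spanning 0--100: the identity curve
#' (perfect calibration) integrates to exactly 5000, constant 100% coverage
#' to 10000 and constant 0% coverage to 0.
#'
#' @param curve a [coverage_curve()] (or data frame with `level` and
#'   `coverage` in percent).
#' @param anchor when the supplied grid stops short of the endpoints
#'   (coverage curves are evaluated on 1--99), extend it with the limits of
#'   the conformal construction: a 0%-confidence interval is empty
#'   (coverage 0) and a 100%-confidence interval is unbounded
#'   (coverage 100). Default `TRUE`.
#' @return the area (percent x percent scale).
#' @export
coverage_auc <- function(curve, anchor = TRUE) {
  lv <- curve$level; cv <- curve$coverage
  stop_if_not(all(diff(lv) > 0), "levels must be strictly increasing")
  if (anchor) {
    if (lv[1] > 0) { lv <- c(0, lv); cv <- c(0, cv) }
    if (lv[length(lv)] < 100) { lv <- c(lv, 100); cv <- c(cv, 100) }
  }
  stop_if_not(lv[1] <= 1e-9 && lv[length(lv)] >= 100 - 1e-9,
              "grid must span 0-100 (set anchor = TRUE or supply endpoints)")
  sum(diff(lv) * (utils::head(cv, -1) + cv[-1]) / 2)
}

#' Two-sided Wilcoxon signed-rank test for paired session metrics
#'
#' Tests whether paired per-session metrics (e.g. RMSEs of two models on the
#' same subject-sessions) differ systematically. Zero differences are
#' discarded; with 25 or fewer untied pairs the exact signed-rank null
#' distribution is used, otherwise the normal approximation with tie
#' correction.
#'
#' @param a,b paired numeric vectors.
#' @return a list of class `signed_rank_test` with `statistic` (V, the sum of
#'   positive-difference ranks), `n` (nonzero pairs), `p_value` (two-sided)
#'   and `method`.
#' @export
paired_signed_rank <- function(a, b) {
  stop_if_not(length(a) == length(b), "inputs must be paired")
  d <- a - b
  d <- d[is.finite(d) & d != 0]
  n <- length(d)
  stop_if_not(n >= 2, "fewer than 2 nonzero differences")
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (n <= 25 && !ties) {
    # exact two-sided p from the signed-rank null distribution
    lower <- stats::psignrank(V, n)
    upper <- 1 - stats::psignrank(V - 1, n)
    p <- min(1, 2 * min(lower, upper))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_sizes <- table(abs(d))
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_sizes^3 - tie_sizes) / 48
    z <- (V - mu) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  structure(list(statistic = V, n = n, p_value = p, method = method),
            class = "signed_rank_test")
}

#' @export
print.signed_rank_test <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank (%s): V = %g, n = %d, p = %.4g\n",
              x$method, x$statistic, x$n, x$p_value))
  invisible(x)
}

#' Percent reduction relative to a reference
#'
#' `100 (reference - value) / reference`, rounded half-even to one decimal:
#' a model RMSE of 0.29 against a reference of 0.35 is a 17.1% reduction.
#'
#' @param reference positive reference value.
#' @param value comparison value.
#' @return percent reduction, one decimal.
#' @export
percent_reduction <- function(reference, value) {
  stop_if_not(all(reference > 0), "reference must be positive")
  round(100 * (reference - value) / reference, 1)
}

#' Per-stratum residual standard deviation summary
#'
#' @param y_hat,y paired predictions and observations.
#' @param edges interior bin edges over `y_hat` (e.g. `scope$edges`);
#'   empty for a single overall bin.
#' @return data frame `bin, n, sigma`.
#' @export
residual_summary <- function(y_hat, y, edges = numeric()) {
  stop_if_not(length(y_hat) == length(y), "inputs must be paired")
  bin <- assign_bins(y_hat, edges)
  do.call(rbind, lapply(sort(unique(bin)), function(b) {
    r <- y_hat[bin == b] - y[bin == b]
    data.frame(bin = b, n = length(r), sigma = sqrt(mean(r^2)))
  }))
}
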