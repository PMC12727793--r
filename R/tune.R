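#' Session-specific coverage curve under a fitted SCOPE table
#'
#' Evaluates the empirical coverage of the globally calibrated SCOPE
#' intervals on one local dataset (a session, subject or domain) across a
#' confidence grid. The resulting curve is the input to [calibrate_level()].
#'
#' @param table a fitted [fit_scope()] object.
#' @param y_hat local predictions.
#' @param y local observations (same length; at least `min_points`).
#' @param grid confidence grid in percent (default 1--99).
#' @param min_points minimum local sample size (default 10, the session
#'   evaluation filter).
#' @return a [coverage_curve()] data frame.
#' @export
session_coverage_curve <- function(table, y_hat, y, grid = 1:99,
                                   min_points = 10) {
  stop_if_not(length(y_hat) == length(y), "inputs must be paired")
  stop_if_not(length(y) >= min_points,
              "need at least %d valid timepoints, got %d", min_points,
              length(y))
  coverage_curve(function(lv) predict_interval(table, y_hat, lv), y,
                 grid = grid)
}

#' Fine-tune the nominal level to hit a target coverage
#'
#' Finds the smallest nominal confidence level whose realized local coverage
#' reaches the target: the intersection of the target with the
#' monotone-ized (running-maximum) coverage curve, located by linear
#' interpolation between grid points. Sessions that over-cover need a much
#' lower nominal level than the target (narrower intervals at the same
#' realized coverage); if the curve never reaches the target the maximum
#' grid level is returned with `reachable = FALSE`.
#'
#' @param curve a [coverage_curve()] (levels and coverage in percent).
#' @param target target coverage in percent, inside (0, 100).
#' @param scope_id identifier echoed in the result (default `NA`).
#' @return object of class `local_calibration`: a one-row data frame
#'   `scope_id, target, level, achieved, reachable` where `level` is the
#'   calibrated nominal level (percent).
#' @export
calibrate_level <- function(curve, target, scope_id = NA_character_) {
  stop_if_not(target > 0 && target < 100, "target must lie inside (0, 100)")
  lv <- curve$level
  cv <- cummax(curve$coverage)           # enforce monotone coverage
  if (max(cv) < target) {
    out <- data.frame(scope_id = scope_id, target = target,
                      level = lv[length(lv)], achieved = cv[length(cv)],
                      reachable = FALSE, stringsAsFactors = FALSE)
  } else {
    i <- which(cv >= target)[1]
    level <- if (i == 1 || cv[i] == target) {
      lv[i]
    } else {
      # linear interpolation across the crossing segment
      lv[i - 1] + (target - cv[i - 1]) / (cv[i] - cv[i - 1]) *
        (lv[i] - lv[i - 1])
    }
    out <- data.frame(scope_id = scope_id, target = target, level = level,
                      achieved = target, reachable = TRUE,
                      stringsAsFactors = FALSE)
  }
  class(out) <- c("local_calibration", class(out))
  out
}
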