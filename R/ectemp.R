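#' Extended-Kalman-filter parameters for heart-rate-based CBT estimation
#'
#' Scalar-state EKF in the style of the published heart-rate core-temperature
#' estimators: the state is core temperature CT with a random-walk time
#' update, observed through a nonlinear heart-rate mapping m(CT). Defaults
#' follow the published quadratic model of Buller et al. (2013):
#' `m(CT) = -7887.1 + 384.4286 CT - 4.5714 CT^2`, process-noise variance
#' 0.000484 degC^2/min, observation-noise variance 356.4458 bpm^2, and
#' initialisation at 37.1 degC with variance 0.01 degC^2. A sigmoid mapping
#' family is available as an alternative.
#'
#' @param init_ct initial CT estimate, degC (default 37.1).
#' @param init_var initial variance, degC^2 (default 0.01).
#' @param q process-noise variance, degC^2 per minute.
#' @param r observation-noise variance, bpm^2.
#' @param mapping `"quadratic"` or `"sigmoid"`.
#' @param coef mapping coefficients: for quadratic, `c(a, b, c)` of
#'   `a + b CT + c CT^2`; for sigmoid, `c(lo, hi, mid, scale)` of
#'   `lo + (hi - lo) / (1 + exp(-(CT - mid)/scale))`.
#' @param burn_in minutes flagged as initialisation-dependent and excluded
#'   from evaluation (default 30).
#' @return object of class `ekf_params`.
#' @export
ekf_params <- function(init_ct = 37.1, init_var = 0.01,
                       q = 0.000484, r = 356.4458,
                       mapping = c("quadratic", "sigmoid"),
                       coef = NULL, burn_in = 30) {
  stop_if_not(init_var >= 0, "initial variance must be >= 0")
  stop_if_not(q >= 0 && r >= 0, "noise variances must be >= 0")
  stop_if_not(is.numeric(burn_in) && burn_in >= 0, "burn_in must be >= 0")
  mapping <- match.arg(mapping)
  if (is.null(coef))
    coef <- if (mapping == "quadratic") c(-7887.1, 384.4286, -4.5714)
            else c(60, 180, 38.5, 1.5)
  stop_if_not(length(coef) == if (mapping == "quadratic") 3L else 4L,
              "wrong number of mapping coefficients")
  structure(list(init_ct = init_ct, init_var = init_var, q = q, r = r,
                 mapping = mapping, coef = coef,
                 burn_in = as.integer(burn_in)),
            class = "ekf_params")
}

ekf_map <- function(ct, params) {
  cf <- params$coef
  if (params$mapping == "quadratic") cf[1] + cf[2] * ct + cf[3] * ct^2
  else cf[1] + (cf[2] - cf[1]) / (1 + exp(-(ct - cf[3]) / cf[4]))
}

ekf_map_deriv <- function(ct, params) {
  cf <- params$coef
  if (params$mapping == "quadratic") cf[2] + 2 * cf[3] * ct
  else {
    s <- 1 / (1 + exp(-(ct - cf[3]) / cf[4]))
    (cf[2] - cf[1]) * s * (1 - s) / cf[4]
  }
}

#' Initialise the EKF state
#'
#' @param params an [ekf_params()] object.
#' @return object of class `ekf_state` with fields `ct`, `var`, `minute`.
#' @export
ekf_init <- function(params = ekf_params()) {
  stop_if_not(inherits(params, "ekf_params"), "params must come from ekf_params()")
  structure(list(ct = params$init_ct, var = params$init_var, minute = 0L),
            class = "ekf_state")
}

#' One EKF minute step
#'
#' Time update `CT- = CT, P- = P + q`; if a heart-rate observation is
#' present, linearise the mapping at the prior (`H = m'(CT-)`), form the gain
#' `K = P- H / (H^2 P- + r)` and apply the measurement update
#' `CT+ = CT- + K (HR - m(CT-))`, `P+ = (1 - K H) P-`. A missing observation
#' applies the time update only.
#'
#' @param state an `ekf_state`.
#' @param hr heart-rate observation in bpm, or `NA` for a missing minute.
#' @param params an [ekf_params()].
#' @return the updated `ekf_state`.
#' @export
ekf_step <- function(state, hr, params = ekf_params()) {
  stop_if_not(is.finite(state$ct) && is.finite(state$var),
              "state must be finite")
  ct <- state$ct
  P <- state$var + params$q
  if (!is.na(hr)) {
    H <- ekf_map_deriv(ct, params)
    denom <- H^2 * P + params$r
    stop_if_not(denom > 0,
                "degenerate update: H^2 P + r is zero with an observation present")
    K <- P * H / denom
    ct <- ct + K * (hr - ekf_map(ct, params))
    P <- (1 - K * H) * P
  }
  structure(list(ct = ct, var = max(P, 0), minute = state$minute + 1L),
            class = "ekf_state")
}

#' Run the EKF over a heart-rate series
#'
#' Applies [ekf_step()] minute by minute; the square root of the filtered
#' variance is reported as the prediction uncertainty, and minutes up to the
#' burn-in are flagged as excluded from evaluation because they still depend
#' on the initialisation.
#'
#' @param hr numeric heart-rate series on a 1-minute grid (`NA` allowed).
#' @param params an [ekf_params()].
#' @return data frame of class `ekf_run` with columns
#'   `minute, ct, sd, burn_in`.
#' @export
ekf_run <- function(hr, params = ekf_params()) {
  stop_if_not(length(hr) >= 1, "heart-rate series is empty")
  state <- ekf_init(params)
  ct <- numeric(length(hr)); sd_ <- numeric(length(hr))
  for (t in seq_along(hr)) {
    state <- ekf_step(state, hr[t], params)
    ct[t] <- state$ct
    sd_[t] <- sqrt(state$var)
  }
  out <- data.frame(minute = seq_along(hr), ct = ct, sd = sd_,
                    burn_in = seq_along(hr) <= params$burn_in)
  class(out) <- c("ekf_run", class(out))
  out
}

#' Gaussian prediction intervals from an EKF run
#'
#' The filter reports a state standard deviation rather than conformal
#' quantiles; intervals are therefore the Gaussian
#' `CT +/- z(level) * sd` with `z` the two-sided normal quantile (so the
#' 0.6827 level gives `CT +/- 1 sd`).
#'
#' @param run an [ekf_run()] result.
#' @param level confidence level in (0, 1).
#' @return data frame of class `prediction_interval` with columns
#'   `y_hat, lower, upper, level, stratum` (stratum is `NA`: the filter has
#'   no strata) plus `minute` and `burn_in` carried over.
#' @export
ekf_intervals <- function(run, level = 0.9545) {
  stop_if_not(inherits(run, "ekf_run"), "run must come from ekf_run()")
  stop_if_not(length(level) == 1 && level > 0 && level < 1,
              "level must lie in (0, 1)")
  z <- stats::qnorm((1 + level) / 2)
  out <- data.frame(y_hat = run$ct, lower = run$ct - z * run$sd,
                    upper = run$ct + z * run$sd, level = level,
                    stratum = NA_integer_, minute = run$minute,
                    burn_in = run$burn_in)
  class(out) <- c("prediction_interval", class(out))
  out
}
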