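#' Alert engine configuration
#'
#' Defines the ordered temperature bands for the four-state alert ladder and
#' the classification policy. The default bands follow the standard clinical
#' ladder: Nominal 36.5--37.75 degC; Advisory 36--36.5 and 37.75--38;
#' Caution 35--36 and 38--38.9; Warning below 35 or above 38.9. Each band is
#' closed at its lower edge and open at its upper edge, so every finite
#' temperature maps to exactly one state.
#'
#' @param bands data frame with columns `state`, `lower`, `upper` whose
#'   half-open intervals `[lower, upper)` partition the real line. Defaults
#'   to the four-state ladder above.
#' @param severity character vector naming the states from least to most
#'   severe (default Nominal < Advisory < Caution < Warning). Custom `bands`
#'   may use any subset/ordering declared here.
#' @param level confidence level at which intervals feed the engine
#'   (default 0.6827, the 68% operating point).
#' @param policy `"adverse-bound"` (default): the state is the more severe
#'   of the upper bound judged against the hot-side bands and the lower
#'   bound judged against the cold-side bands; `"point"`: classify the point
#'   prediction only.
#' @param persistence consecutive qualifying minutes required before
#'   escalating to a more severe state (default 1 = immediate);
#'   de-escalation is always immediate.
#' @return object of class `alert_config`.
#' @export
alert_config <- function(bands = NULL,
                         severity = c("Nominal", "Advisory", "Caution",
                                      "Warning"),
                         level = 0.6827,
                         policy = c("adverse-bound", "point"),
                         persistence = 1) {
  if (is.null(bands)) {
    bands <- data.frame(
      state = c("Warning", "Caution", "Advisory", "Nominal", "Advisory",
                "Caution", "Warning"),
      lower = c(-Inf, 35, 36, 36.5, 37.75, 38, 38.9),
      upper = c(35, 36, 36.5, 37.75, 38, 38.9, Inf),
      stringsAsFactors = FALSE)
  }
  stop_if_not(all(c("state", "lower", "upper") %in% names(bands)),
              "bands needs columns state, lower, upper")
  bands <- bands[order(bands$lower), , drop = FALSE]
  stop_if_not(bands$lower[1] == -Inf &&
                bands$upper[nrow(bands)] == Inf &&
                all(bands$upper[-nrow(bands)] == bands$lower[-1]),
              "bands must partition the real line (contiguous half-open intervals)")
  stop_if_not(all(bands$state %in% severity),
              "every band state must appear in the severity ordering")
  stop_if_not(is_count(persistence), "persistence must be a positive integer")
  stop_if_not(level > 0 && level < 1, "level must lie in (0, 1)")
  structure(list(bands = bands, severity = severity, level = level,
                 policy = match.arg(policy),
                 persistence = as.integer(persistence)),
            class = "alert_config")
}

severity_rank <- function(config, state) match(state, config$severity)

#' Classify a temperature against the alert bands
#'
#' @param config an [alert_config()].
#' @param value temperature(s) in degC (finite).
#' @return character state(s).
#' @export
classify_point <- function(config, value) {
  stop_if_not(inherits(config, "alert_config"),
              "config must come from alert_config()")
  stop_if_not(all(is.finite(value)), "value must be finite")
  i <- findInterval(value, config$bands$lower)
  config$bands$state[i]
}

# most severe hot-side (or cold-side) state reachable by a bound, obtained by
# clamping the bound at the neutral point so the opposite side cannot fire
neutral_point <- function(config) {
  least <- config$bands[severity_rank(config, config$bands$state) ==
                          min(severity_rank(config, config$bands$state)), ]
  mean(c(max(least$lower[1], 30), min(least$upper[1], 45)))
}

#' Classify a prediction interval
#'
#' Under the default adverse-bound policy the upper bound is judged against
#' the hot-side bands and the lower bound against the cold-side bands, and
#' the more severe state wins; enlarging an interval can therefore never
#' lower the severity. The `"point"` policy classifies the point prediction
#' only. A zero-width interval reduces to [classify_point()] under either
#' policy.
#'
#' @param config an [alert_config()].
#' @param interval one-row (or many-row) interval data frame with
#'   `y_hat, lower, upper` columns; a `minute`/`time` column is echoed.
#' @return data frame of class `alert_events`: `time, state, bound, y_hat,
#'   lower, upper`, where `bound` records which bound triggered the state.
#' @export
classify_interval <- function(config, interval) {
  stop_if_not(inherits(config, "alert_config"),
              "config must come from alert_config()")
  stop_if_not(all(interval$lower <= interval$upper),
              "invalid interval: lower > upper")
  time <- interval$time %||% interval$minute %||% seq_len(nrow(interval))
  if (config$policy == "point") {
    st <- classify_point(config, interval$y_hat)
    bound <- rep("point", nrow(interval))
  } else {
    np <- neutral_point(config)
    hot <- classify_point(config, pmax(interval$upper, np))
    cold <- classify_point(config, pmin(interval$lower, np))
    hot_wins <- severity_rank(config, hot) >= severity_rank(config, cold)
    st <- ifelse(hot_wins, hot, cold)
    bound <- ifelse(hot_wins, "upper", "lower")
  }
  out <- data.frame(time = time, state = st, bound = bound,
                    y_hat = interval$y_hat, lower = interval$lower,
                    upper = interval$upper, stringsAsFactors = FALSE)
  class(out) <- c("alert_events", class(out))
  out
}

#' Streamed alerts with escalation persistence
#'
#' Applies [classify_interval()] minute by minute; escalation to a more
#' severe state is emitted only once the raw classification has been at
#' least that severe for `persistence` consecutive minutes, while
#' de-escalation is immediate. With `persistence = 1` the output equals the
#' pointwise classification.
#'
#' @param config an [alert_config()].
#' @param intervals time-ordered interval data frame (`time` or `minute`
#'   column strictly increasing).
#' @return `alert_events` data frame with the emitted `state` and the raw
#'   pointwise state in `raw_state`.
#' @export
stream_alerts <- function(config, intervals) {
  raw <- classify_interval(config, intervals)
  stop_if_not(all(diff(raw$time) > 0), "interval series must be time-ordered")
  rk <- severity_rank(config, raw$state)
  emitted <- integer(length(rk))
  cur <- 1L
  p <- config$persistence
  for (t in seq_along(rk)) {
    if (rk[t] <= cur) {
      cur <- rk[t]                       # de-escalate immediately
    } else {
      # escalate to the highest severity sustained over the last p minutes
      lo <- max(1L, t - p + 1L)
      if (t - lo + 1L == p) {
        sustained <- min(rk[lo:t])
        if (sustained > cur) cur <- sustained
      }
    }
    emitted[t] <- cur
  }
  raw$raw_state <- raw$state
  raw$state <- config$severity[emitted]
  raw
}
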