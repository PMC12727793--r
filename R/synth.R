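#' Configuration for the synthetic heat-stress cohort generator
#'
#' Builds the parameter set for [generate_cohort()]. Defaults are calibrated
#' so that a cohort of 50+ subjects spans the physiological CBT range seen in
#' operational heat-stress data (roughly 36.1--40.3 degC), with observation
#' noise that grows above a knee temperature (heteroscedasticity at high CBT)
#' and occasional missing values in every measured column.
#'
#' The latent core temperature follows a first-order relaxation model on a
#' 1-minute grid:
#' \deqn{C_{t+1} = C_t + a\,w_t + b\,\mathrm{clo}\,\max(T_{amb}-24, 0)
#'       - c\,(C_t - 37) + \eta_t}
#' where \eqn{w_t} is work intensity, clo the clothing insulation, and
#' \eqn{\eta_t} white process noise. Heart rate is a baseline plus linear work
#' and thermal terms (so it can rise independently of CBT); chest skin
#' temperature is a convex combination of core and ambient temperature.
#'
#' @param n_subjects subjects per domain (default 10).
#' @param domains character vector of domain labels; each gets its own
#'   ambient-temperature and clothing range.
#' @param session_minutes length-2 range of session durations, minutes.
#' @param sessions_per_subject length-2 integer range.
#' @param gain_work degC per minute per unit work intensity.
#' @param gain_heat degC per minute per clo per degC of ambient excess over
#'   24 degC.
#' @param relax relaxation rate toward the 37 degC set point, per minute
#'   (must be > 0).
#' @param process_sd sd of the per-minute white noise on the latent CBT, degC.
#' @param hr_noise_sd,skin_noise_sd observation noise sds (bpm, degC).
#' @param cbt_noise_sd baseline CBT observation noise sd, degC.
#' @param hetero_slope extra CBT noise sd per degC above `hetero_knee`.
#' @param hetero_knee knee temperature for heteroscedastic CBT noise, degC.
#' @param missing_rates named vector of per-column masking probabilities in
#'   \[0, 1\] (columns among heart_rate, skin_temp, ambient_temp,
#'   work_intensity, clothing, cbt).
#' @param max_changes maximum number of level changes per session for the
#'   semi-sequential columns (ambient, work intensity, clothing).
#' @param rest_prob probability that a work segment is rest (zero intensity).
#' @param seed integer RNG seed; fixed seed gives a byte-identical cohort.
#' @return an object of class `synth_config` (a validated list).
#' @seealso [generate_cohort()], [inject_missingness()], [oracle_predictor()]
#' @export
synth_config <- function(n_subjects = 10,
                         domains = c("WFF", "RACE", "MINE", "NUC", "EOD", "FACT"),
                         session_minutes = c(60, 180),
                         sessions_per_subject = c(1, 2),
                         gain_work = 0.018,
                         gain_heat = 0.0018,
                         relax = 0.025,
                         process_sd = 0.03,
                         hr_noise_sd = 3,
                         skin_noise_sd = 0.3,
                         cbt_noise_sd = 0.1,
                         hetero_slope = 0.2,
                         hetero_knee = 38,
                         missing_rates = c(heart_rate = 0.05, skin_temp = 0.05,
                                           ambient_temp = 0.01,
                                           work_intensity = 0.01,
                                           clothing = 0.01, cbt = 0.02),
                         max_changes = 3,
                         rest_prob = 0.3,
                         seed = 1L) {
  stop_if_not(is_count(n_subjects), "n_subjects must be a positive integer")
  stop_if_not(length(domains) >= 1 && !anyDuplicated(domains),
              "domains must be distinct labels")
  stop_if_not(length(session_minutes) == 2 && all(session_minutes >= 1) &&
                session_minutes[1] <= session_minutes[2],
              "session_minutes must be an increasing positive range")
  stop_if_not(relax > 0, "relaxation rate must be > 0")
  stop_if_not(all(missing_rates >= 0 & missing_rates <= 1),
              "missing rates must lie in [0, 1]")
  stop_if_not(rest_prob >= 0 && rest_prob <= 1, "rest_prob must lie in [0, 1]")
  structure(list(
    n_subjects = as.integer(n_subjects), domains = domains,
    session_minutes = as.integer(session_minutes),
    sessions_per_subject = as.integer(sessions_per_subject),
    gain_work = gain_work, gain_heat = gain_heat, relax = relax,
    process_sd = process_sd, hr_noise_sd = hr_noise_sd,
    skin_noise_sd = skin_noise_sd, cbt_noise_sd = cbt_noise_sd,
    hetero_slope = hetero_slope, hetero_knee = hetero_knee,
    missing_rates = missing_rates, max_changes = as.integer(max_changes),
    rest_prob = rest_prob, seed = seed
  ), class = "synth_config")
}

# per-domain environmental envelopes: ambient range (degC) and clothing
# range (clo); encapsulated domains run hotter / heavier
domain_envelope <- function(domain) {
  switch(domain,
    WFF  = list(ambient = c(25, 44), clo = c(1.0, 1.6)),
    RACE = list(ambient = c(22, 40), clo = c(0.8, 1.4)),
    MINE = list(ambient = c(18, 35), clo = c(0.5, 1.2)),
    NUC  = list(ambient = c(18, 30), clo = c(0.8, 1.4)),
    EOD  = list(ambient = c(20, 38), clo = c(1.2, 1.8)),
    FACT = list(ambient = c(18, 32), clo = c(0.4, 1.0)),
    list(ambient = c(18, 40), clo = c(0.5, 1.5))
  )
}

#' Body surface area by the DuBois formula
#'
#' @param mass body mass in kg.
#' @param height height in cm.
#' @return body surface area in square metres.
#' @export
bsa_dubois <- function(mass, height) {
  stop_if_not(all(mass > 0) && all(height > 0), "mass and height must be > 0")
  0.007184 * mass^0.425 * height^0.725
}

# uniform integer draw on [a, b] that is safe for a == b (sample() would
# otherwise treat the scalar as an upper bound)
sample_range <- function(a, b) if (a >= b) a else sample(seq(a, b), 1L)

# piecewise-constant series: <= n_changes level changes over `len` minutes
piecewise_series <- function(len, n_changes, draw_level) {
  k <- sample.int(n_changes + 1L, 1L)          # number of segments
  cuts <- if (k > 1) sort(sample(seq_len(len - 1L), k - 1L)) else integer()
  bounds <- c(0L, cuts, len)
  lens <- diff(bounds)
  rep(vapply(seq_len(k), function(i) draw_level(), numeric(1)), lens)
}

#' Generate a synthetic multi-domain heat-stress cohort
#'
#' Simulates per-subject sessions of heart rate, chest skin temperature,
#' ambient temperature, work intensity, clothing insulation and observed core
#' body temperature on a 1-minute grid, plus static demographics, following
#' the relaxation model described in [synth_config()]. Missing values are then
#' injected per the configured rates. Deterministic for a fixed seed.
#'
#' @param config a [synth_config()] object.
#' @return an object of class `heat_cohort`: a list with elements
#'   `sessions` (long data frame, one row per subject-session-minute, columns
#'   `subject_id, session_id, time, heart_rate, skin_temp, ambient_temp,
#'   work_intensity, clothing, cbt`), `subjects` (one row per subject:
#'   `subject_id, domain, age, sex, mass, height, bsa`) and `config`.
#' @examples
#' coh <- generate_cohort(synth_config(n_subjects = 2, domains = "WFF"))
#' head(coh$sessions)
#' @export
generate_cohort <- function(config = synth_config()) {
  stop_if_not(inherits(config, "synth_config"),
              "config must be built by synth_config()")
  with_seed(config$seed, {
    subjects <- list(); sessions <- list(); sid <- 0L
    for (domain in config$domains) {
      env <- domain_envelope(domain)
      for (i in seq_len(config$n_subjects)) {
        sid <- sid + 1L
        subject_id <- sprintf("%s_%02d", domain, i)
        mass <- runif(1, 55, 100)
        height <- runif(1, 155, 195)
        subjects[[sid]] <- data.frame(
          subject_id = subject_id, domain = domain,
          age = round(runif(1, 18, 60)),
          sex = sample(c("M", "F"), 1L),
          mass = round(mass, 1), height = round(height, 1),
          bsa = round(bsa_dubois(mass, height), 3),
          stringsAsFactors = FALSE)
        hr_base <- runif(1, 58, 75)
        n_sess <- sample_range(config$sessions_per_subject[1],
                               config$sessions_per_subject[2])
        for (s in seq_len(n_sess)) {
          len <- sample_range(config$session_minutes[1],
                              config$session_minutes[2])
          ambient <- piecewise_series(len, config$max_changes,
            function() runif(1, env$ambient[1], env$ambient[2]))
          work <- piecewise_series(len, config$max_changes,
            function() if (runif(1) < config$rest_prob) 0 else runif(1, 0.5, 3))
          clo <- piecewise_series(len, min(1L, config$max_changes),
            function() runif(1, env$clo[1], env$clo[2]))
          cbt_true <- numeric(len)
          C <- runif(1, 36.1, 37.3)
          for (t in seq_len(len)) {
            C <- C + config$gain_work * work[t] +
              config$gain_heat * clo[t] * max(ambient[t] - 24, 0) -
              config$relax * (C - 37) +
              rnorm(1, 0, config$process_sd)
            cbt_true[t] <- C
          }
          noise_sd <- config$cbt_noise_sd +
            config$hetero_slope * pmax(cbt_true - config$hetero_knee, 0)
          cbt_obs <- pmin(pmax(cbt_true + rnorm(len, 0, noise_sd), 35), 41)
          hr <- pmin(pmax(hr_base + 22 * work + 16 * (cbt_true - 37) +
                            rnorm(len, 0, config$hr_noise_sd), 40), 210)
          skin <- 0.85 * cbt_true + 0.15 * ambient +
            rnorm(len, 0, config$skin_noise_sd)
          sessions[[length(sessions) + 1L]] <- data.frame(
            subject_id = subject_id, session_id = sprintf("%s_s%d", subject_id, s),
            time = seq_len(len),
            heart_rate = round(hr, 1), skin_temp = round(skin, 2),
            ambient_temp = round(ambient, 1),
            work_intensity = round(work, 2), clothing = round(clo, 2),
            cbt = round(cbt_obs, 3), stringsAsFactors = FALSE)
        }
      }
    }
    sessions <- do.call(rbind, sessions)
    rownames(sessions) <- NULL
    sessions <- inject_missingness(sessions, config$missing_rates,
                                   seed = NULL)  # inherits the cohort RNG
    cohort <- list(sessions = sessions,
                   subjects = do.call(rbind, subjects),
                   config = config)
    class(cohort) <- "heat_cohort"
    cohort
  })
}

#' @export
print.heat_cohort <- function(x, ...) {
  cat("Synthetic heat-stress cohort\n")
  cat(sprintf("  domains:  %s\n", paste(unique(x$subjects$domain), collapse = ", ")))
  cat(sprintf("  subjects: %d   sessions: %d   timepoints: %d\n",
              nrow(x$subjects), length(unique(x$sessions$session_id)),
              nrow(x$sessions)))
  cbt <- x$sessions$cbt
  cat(sprintf("  observed CBT range: %.2f-%.2f degC (%.1f%% missing)\n",
              min(cbt, na.rm = TRUE), max(cbt, na.rm = TRUE),
              100 * mean(is.na(cbt))))
  invisible(x)
}

#' Independently mask cells of a session table
#'
#' Each eligible cell is set to `NA` with its column's probability,
#' independently across cells. Used by [generate_cohort()] and available
#' directly for experiments on missing-data handling.
#'
#' @param frames session data frame (long format, see [generate_cohort()]).
#' @param rates named numeric vector of probabilities in \[0, 1\]; names must
#'   be columns of `frames`. Include `cbt` explicitly if targets should be
#'   masked.
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return `frames` with masked cells set to `NA`.
#' @export
inject_missingness <- function(frames, rates, seed = NULL) {
  stop_if_not(is.data.frame(frames), "frames must be a data frame")
  stop_if_not(all(rates >= 0 & rates <= 1), "rates must lie in [0, 1]")
  stop_if_not(!is.null(names(rates)) && all(names(rates) %in% names(frames)),
              "every rate must be named after a column of frames")
  with_seed(seed, {
    for (col in names(rates)) {
      r <- rates[[col]]
      if (r > 0) {
        mask <- runif(nrow(frames)) < r
        frames[[col]][mask] <- NA
      }
    }
    frames
  })
}

#' Oracle predictor with a known noise model
#'
#' Returns per-timepoint "predictions" built as the observed CBT plus noise
#' drawn from a stated (possibly heteroscedastic) model:
#' \eqn{sd(y) = sd_0 + slope \cdot \max(y - knee, 0)}. Because the error
#' process is known exactly, this predictor lets the conformal calibration
#' layer be validated independently of any trained model.
#'
#' @param frames session data frame containing observed `cbt`.
#' @param sd0 baseline noise sd, degC.
#' @param slope extra sd per degC above `knee`.
#' @param knee knee temperature, degC.
#' @param seed RNG seed; fixed seed gives identical predictions.
#' @return data frame `subject_id, session_id, time, y, y_hat`; rows with
#'   missing CBT are skipped and their count is attached as attribute
#'   `n_skipped` (and reported via a message when nonzero).
#' @export
oracle_predictor <- function(frames, sd0 = 0.1, slope = 0.3, knee = 38,
                             seed = 1L) {
  stop_if_not(is.data.frame(frames) && "cbt" %in% names(frames),
              "frames must contain a cbt column")
  stop_if_not(sd0 >= 0 && slope >= 0, "noise parameters must be >= 0")
  keep <- !is.na(frames$cbt)
  n_skipped <- sum(!keep)
  if (n_skipped > 0)
    message(sprintf("oracle_predictor: skipped %d timepoints with missing CBT",
                    n_skipped))
  y <- frames$cbt[keep]
  with_seed(seed, {
    sd_y <- sd0 + slope * pmax(y - knee, 0)
    out <- data.frame(
      subject_id = frames$subject_id[keep] %||% NA,
      session_id = frames$session_id[keep] %||% NA,
      time = frames$time[keep] %||% seq_along(y),
      y = y,
      y_hat = y + rnorm(length(y), 0, sd_y),
      stringsAsFactors = FALSE)
    attr(out, "n_skipped") <- n_skipped
    out
  })
}
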