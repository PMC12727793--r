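# shared fixtures, all generated in code

FEATURE_COLS <- c("heart_rate", "skin_temp", "ambient_temp",
                  "work_intensity", "clothing")

# missingness config: features complete, optional missing targets
rates_cbt_only <- function(cbt = 0.02)
  c(heart_rate = 0, skin_temp = 0, ambient_temp = 0, work_intensity = 0,
    clothing = 0, cbt = cbt)

# small deterministic cohort reused across prep/model tests
small_cohort <- function(seed = 101, n_subjects = 3,
                         domains = c("WFF", "RACE", "EOD"), ...) {
  generate_cohort(synth_config(n_subjects = n_subjects, domains = domains,
                               session_minutes = c(40, 80), seed = seed, ...))
}

# hand-built windowed dataset with controllable targets and features
toy_windows <- function(n = 50, width = 5, static_dim = 3, y = NULL,
                        seed = 1) {
  set.seed(seed)
  structure(list(
    seq = array(rnorm(n * width * 2), c(n, width, 2)),
    static = matrix(rnorm(n * static_dim), n, static_dim),
    y = if (is.null(y)) rnorm(n, 37, 0.5) else rep_len(y, n),
    provenance = data.frame(subject_id = paste0("s", rep(1:5, length.out = n)),
                            session_id = paste0("ss", rep(1:5, length.out = n)),
                            end_time = seq_len(n)),
    config = window_config(width = width)),
    class = "windowed_dataset")
}

# exchangeable heteroscedastic oracle pairs: y drawn from a cohort-like
# mixture, y_hat = y + noise with sd growing above 38 degC
oracle_pairs <- function(n, seed = 1, sd0 = 0.1, slope = 0.3, knee = 38) {
  set.seed(seed)
  y <- c(rnorm(ceiling(n * 0.7), 37.2, 0.4),
         runif(floor(n * 0.3), 37.5, 40.3))[1:n]
  y <- sample(y)                         # exchangeable ordering
  sd_y <- sd0 + slope * pmax(y - knee, 0)
  list(y = y, y_hat = y + rnorm(n, 0, sd_y))
}
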