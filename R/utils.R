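# internal helpers shared across modules

# Evaluate `expr` with a temporary RNG state seeded by `seed`, restoring the
# caller's RNG afterwards so package functions never clobber user randomness.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

stop_if_not <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == floor(x)

# column order of the per-minute session table
SESSION_COLUMNS <- c("subject_id", "session_id", "time", "heart_rate",
                     "skin_temp", "ambient_temp", "work_intensity",
                     "clothing", "cbt")

SUBJECT_COLUMNS <- c("subject_id", "domain", "age", "sex", "mass",
                     "height", "bsa")

FEATURE_COLUMNS <- c("heart_rate", "skin_temp", "ambient_temp",
                     "work_intensity", "clothing")
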