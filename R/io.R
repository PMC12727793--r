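#' Read and write session tables
#'
#' Sessions are stored as plain CSV, one row per subject-session-minute,
#' with the documented header `subject_id, session_id, time, heart_rate,
#' skin_temp, ambient_temp, work_intensity, clothing, cbt`. Reading checks
#' the schema and reports any missing mandatory column by name; unknown
#' extra columns are preserved with a warning. Writing then reading a table
#' is lossless.
#'
#' @param path CSV file path.
#' @return `read_sessions()`: the session data frame.
#' @export
read_sessions <- function(path) {
  stop_if_not(file.exists(path), "no such file: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(SESSION_COLUMNS, names(df))
  stop_if_not(length(missing_cols) == 0,
              "session CSV is missing mandatory column(s): %s",
              paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(df), SESSION_COLUMNS)
  if (length(extra) > 0)
    warning("unknown column(s) preserved: ", paste(extra, collapse = ", "))
  df[c(SESSION_COLUMNS, extra)]
}

#' @rdname read_sessions
#' @param frames session data frame to write.
#' @export
write_sessions <- function(frames, path) {
  stop_if_not(all(SESSION_COLUMNS %in% names(frames)),
              "frames lack mandatory session columns")
  utils::write.csv(frames, path, row.names = FALSE)
  invisible(path)
}

#' Read and write subject tables
#'
#' Subjects CSV header: `subject_id, domain, age, sex, mass, height, bsa`.
#'
#' @param path CSV file path.
#' @return `read_subjects()`: the subject data frame.
#' @export
read_subjects <- function(path) {
  stop_if_not(file.exists(path), "no such file: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(SUBJECT_COLUMNS, names(df))
  stop_if_not(length(missing_cols) == 0,
              "subject CSV is missing mandatory column(s): %s",
              paste(missing_cols, collapse = ", "))
  df
}

#' @rdname read_subjects
#' @param subjects subject data frame to write.
#' @export
write_subjects <- function(subjects, path) {
  stop_if_not(all(SUBJECT_COLUMNS %in% names(subjects)),
              "subjects lack mandatory columns")
  utils::write.csv(subjects, path, row.names = FALSE)
  invisible(path)
}

#' Serialise a SCOPE table to a versioned JSON document
#'
#' The document stores the stratum edges, member counts, residual sigmas,
#' per-level quantiles, sorted nonconformity scores (so arbitrary levels can
#' be recomputed after deserialisation) and the configuration.
#'
#' @param table a fitted [fit_scope()] object.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return the JSON string (invisibly when written to a file).
#' @export
scope_to_json <- function(table, path = NULL) {
  stop_if_not(inherits(table, "scope"), "table must come from fit_scope()")
  doc <- list(
    format = "heatscope/scope", version = 1L,
    n_cal = table$n_cal, n_strata = table$n_strata,
    edges = table$edges, counts = table$counts, sigma = table$sigma,
    levels = table$config$levels,
    convention = table$config$convention,
    density = table$config$density,
    quantiles = unname(apply(table$quantiles, 1, identity,
                             simplify = FALSE)),
    scores = table$scores)
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(as.character(js)))
  }
  as.character(js)
}

#' @rdname scope_to_json
#' @param json JSON string or file path produced by [scope_to_json()].
#' @return `scope_from_json()`: the reconstructed `scope` object.
#' @export
scope_from_json <- function(json) {
  if (length(json) == 1 && !grepl("^\\s*\\{", json) && file.exists(json))
    json <- paste(readLines(json), collapse = "\n")
  doc <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  stop_if_not(identical(doc$format, "heatscope/scope"),
              "not a SCOPE JSON document")
  cfg <- scope_config(density = doc$density, levels = doc$levels,
                      convention = doc$convention)
  quantiles <- doc$quantiles
  if (is.list(quantiles)) quantiles <- do.call(rbind, quantiles)
  if (is.null(dim(quantiles)))
    quantiles <- matrix(quantiles, nrow = doc$n_strata, byrow = TRUE)
  colnames(quantiles) <- format_level(cfg$levels)
  scores <- if (is.list(doc$scores)) lapply(doc$scores, as.numeric)
            else list(as.numeric(doc$scores))
  structure(list(n_cal = doc$n_cal, n_strata = doc$n_strata,
                 edges = as.numeric(doc$edges %||% numeric()),
                 counts = as.integer(doc$counts),
                 scores = scores, quantiles = quantiles,
                 sigma = as.numeric(doc$sigma), config = cfg),
            class = "scope")
}
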