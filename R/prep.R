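#' Split configuration
#'
#' Parameters for the leakage-free partitioning scheme: one whole domain is
#' held out for the test set, a fixed number of subjects per remaining domain
#' is carved out for test, and the rest is divided into train / validation /
#' calibration at the subject level.
#'
#' @param holdout_domain domain label reserved wholly for the test set.
#' @param k_test_subjects subjects carved out of every other domain for the
#'   test set (default 4).
#' @param ratios named positive ratios for `train`, `validation`,
#'   `calibration`; normalised to sum to 1 (default 60:20:20).
#' @param seed RNG seed for the random subject draws.
#' @return object of class `split_config`.
#' @export
split_config <- function(holdout_domain = "EOD", k_test_subjects = 4,
                         ratios = c(train = 0.6, validation = 0.2,
                                    calibration = 0.2),
                         seed = 1L) {
  stop_if_not(length(holdout_domain) == 1, "one holdout domain expected")
  stop_if_not(is.numeric(k_test_subjects) && k_test_subjects >= 0,
              "k_test_subjects must be >= 0")
  stop_if_not(length(ratios) == 3 && all(ratios > 0),
              "three positive split ratios expected")
  nm <- names(ratios) %||% c("train", "validation", "calibration")
  structure(list(holdout_domain = holdout_domain,
                 k_test_subjects = as.integer(k_test_subjects),
                 ratios = stats::setNames(ratios / sum(ratios), nm),
                 seed = seed),
            class = "split_config")
}

cohort_subset <- function(cohort, subject_ids) {
  out <- list(
    sessions = cohort$sessions[cohort$sessions$subject_id %in% subject_ids, ,
                               drop = FALSE],
    subjects = cohort$subjects[cohort$subjects$subject_id %in% subject_ids, ,
                               drop = FALSE],
    config = cohort$config)
  rownames(out$sessions) <- NULL
  rownames(out$subjects) <- NULL
  class(out) <- class(cohort)
  out
}

#' Carve out the test set
#'
#' Reserves every subject of the holdout domain, plus `k_test_subjects`
#' randomly chosen subjects from each remaining domain, exclusively for the
#' test set. No subject appears in both outputs.
#'
#' @param cohort a cohort list with `sessions` and `subjects` elements (see
#'   [generate_cohort()]).
#' @param config a [split_config()].
#' @return list with cohort subsets `test` and `remainder`.
#' @export
carve_test_set <- function(cohort, config = split_config()) {
  subjects <- cohort$subjects
  stop_if_not(config$holdout_domain %in% subjects$domain,
              "holdout domain '%s' not present in the cohort",
              config$holdout_domain)
  test_ids <- subjects$subject_id[subjects$domain == config$holdout_domain]
  other <- setdiff(unique(subjects$domain), config$holdout_domain)
  with_seed(config$seed, {
    for (domain in other) {
      ids <- subjects$subject_id[subjects$domain == domain]
      stop_if_not(length(ids) > config$k_test_subjects,
                  "domain '%s' has %d subjects; need more than k = %d",
                  domain, length(ids), config$k_test_subjects)
      if (config$k_test_subjects > 0)
        test_ids <- c(test_ids, sample(ids, config$k_test_subjects))
    }
  })
  list(test = cohort_subset(cohort, test_ids),
       remainder = cohort_subset(cohort,
                                 setdiff(subjects$subject_id, test_ids)))
}

#' Grouped train / validation / calibration split
#'
#' Allocates whole subjects (all their measurements) to splits so that the
#' per-split measurement counts approach the target ratios as closely as the
#' subject group sizes allow: subjects are shuffled with the seed, then each
#' is assigned greedily to the split with the largest remaining measurement
#' deficit (ties broken in the order train, validation, calibration).
#'
#' @param cohort cohort subset to partition (typically the `remainder` from
#'   [carve_test_set()]).
#' @param ratios named positive ratios (normalised internally).
#' @param seed RNG seed; the assignment is deterministic per seed.
#' @return object of class `split_assignment`: a data frame
#'   `subject_id, split` with attribute `achieved` giving the realised
#'   measurement proportions.
#' @export
group_split <- function(cohort, ratios = c(train = 0.6, validation = 0.2,
                                           calibration = 0.2),
                        seed = 1L) {
  stop_if_not(all(ratios > 0), "ratios must be positive")
  ratios <- ratios / sum(ratios)
  splits <- names(ratios) %||% paste0("split", seq_along(ratios))
  counts <- table(cohort$sessions$subject_id)
  ids <- unique(cohort$subjects$subject_id)
  stop_if_not(length(ids) >= length(ratios),
              "need at least %d subjects for %d splits",
              length(ratios), length(ratios))
  n_total <- sum(counts[ids])
  targets <- ratios * n_total
  filled <- stats::setNames(numeric(length(splits)), splits)
  assignment <- character(length(ids))
  order_ids <- with_seed(seed, sample(ids))
  for (i in seq_along(order_ids)) {
    deficit <- targets - filled
    pick <- which.max(deficit)          # first max wins ties
    assignment[i] <- splits[pick]
    filled[pick] <- filled[pick] + counts[[order_ids[i]]]
  }
  out <- data.frame(subject_id = order_ids, split = assignment,
                    stringsAsFactors = FALSE)
  out <- out[order(out$subject_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "achieved") <- filled / n_total
  class(out) <- c("split_assignment", class(out))
  out
}

#' @export
print.split_assignment <- function(x, ...) {
  cat("Grouped split assignment:", nrow(x), "subjects\n")
  print(table(x$split))
  cat("achieved measurement proportions:\n")
  print(round(attr(x, "achieved"), 3))
  invisible(x)
}

#' Fit / apply / invert a train-only standard scaler
#'
#' `fit_scaler()` computes per-column means and standard deviations on the
#' training rows only; `apply_scaler()` standardises any table with those
#' statistics (never refitting, so validation/calibration/test are transformed
#' with train statistics alone); `invert_scaler()` undoes the transformation.
#' Columns with zero or undefined spread get their sd replaced by 1 (with a
#' warning) to avoid division by zero.
#'
#' @param train training data frame.
#' @param columns columns to scale (default: the five measured session
#'   features).
#' @return `fit_scaler()`: object of class `scaler_stats` with `mean` and
#'   `sd` vectors; the others return the transformed data frame. The sd is
#'   the population standard deviation (denominator n), so a two-point
#'   column `{36, 38}` has mean 37 and sd 1.
#' @export
fit_scaler <- function(train, columns = FEATURE_COLUMNS) {
  stop_if_not(is.data.frame(train) && nrow(train) > 0,
              "train frames must be a non-empty data frame")
  stop_if_not(all(columns %in% names(train)),
              "missing columns: %s",
              paste(setdiff(columns, names(train)), collapse = ", "))
  mu <- vapply(columns, function(cl) mean(train[[cl]], na.rm = TRUE), 0)
  sd_ <- vapply(columns, function(cl) {
    x <- train[[cl]][!is.na(train[[cl]])]
    if (length(x) == 0) NA_real_ else sqrt(mean((x - mean(x))^2))
  }, 0)
  bad <- !is.finite(sd_) | sd_ == 0
  if (any(bad)) {
    warning("constant or empty column(s) scaled with sd = 1: ",
            paste(columns[bad], collapse = ", "))
    sd_[bad] <- 1
  }
  structure(list(mean = mu, sd = sd_, columns = columns),
            class = "scaler_stats")
}

#' @rdname fit_scaler
#' @param stats a fitted `scaler_stats` object.
#' @param frames data frame to transform.
#' @export
apply_scaler <- function(stats, frames) {
  stop_if_not(inherits(stats, "scaler_stats"), "stats must come from fit_scaler()")
  for (cl in stats$columns)
    frames[[cl]] <- (frames[[cl]] - stats$mean[[cl]]) / stats$sd[[cl]]
  frames
}

#' @rdname fit_scaler
#' @export
invert_scaler <- function(stats, frames) {
  stop_if_not(inherits(stats, "scaler_stats"), "stats must come from fit_scaler()")
  for (cl in stats$columns)
    frames[[cl]] <- frames[[cl]] * stats$sd[[cl]] + stats$mean[[cl]]
  frames
}

#' K-nearest-neighbour imputation against a training reference
#'
#' Replaces every missing feature cell by the mean of that feature over the
#' `k` nearest feature-complete training rows, with distances computed as
#' Euclidean distance over the features observed in the incomplete row
#' (inputs are expected to be standardised already so features are
#' commensurate). Rows are never dropped. When a row has no observed feature
#' at all, every reference row is equidistant and the reference column means
#' are used.
#'
#' @param reference training data frame supplying the donor rows (scaled).
#' @param frames data frame to impute (scaled with the same statistics).
#' @param k number of neighbours (default 5).
#' @param columns feature columns to impute over.
#' @return `frames` with all missing feature cells filled.
#' @export
impute_knn <- function(reference, frames, k = 5,
                       columns = FEATURE_COLUMNS) {
  stop_if_not(is_count(k), "k must be a positive integer")
  stop_if_not(all(columns %in% names(reference)) &&
                all(columns %in% names(frames)),
              "reference and frames must both contain the feature columns")
  all_missing <- vapply(columns, function(cl) all(is.na(reference[[cl]])),
                        TRUE)
  stop_if_not(!any(all_missing),
              "feature(s) missing in every training row: %s",
              paste(columns[all_missing], collapse = ", "))
  R <- as.matrix(reference[columns])
  R <- R[stats::complete.cases(R), , drop = FALSE]
  stop_if_not(nrow(R) >= 1, "no feature-complete training rows available")
  k <- min(k, nrow(R))
  X <- as.matrix(frames[columns])
  incomplete <- which(!stats::complete.cases(X))
  if (length(incomplete) == 0) return(frames)
  pattern <- apply(is.na(X[incomplete, , drop = FALSE]), 1L,
                   function(m) paste(which(m), collapse = ","))
  ref_means <- colMeans(R)
  for (p in unique(pattern)) {
    rows <- incomplete[pattern == p]
    miss_idx <- as.integer(strsplit(p, ",")[[1]])
    obs_idx <- setdiff(seq_along(columns), miss_idx)
    if (length(obs_idx) == 0) {
      for (j in miss_idx) X[rows, j] <- ref_means[j]
      next
    }
    Xo <- X[rows, obs_idx, drop = FALSE]
    Ro <- R[, obs_idx, drop = FALSE]
    # squared Euclidean distances, query rows x reference rows
    d2 <- outer(rowSums(Xo^2), rep(1, nrow(Ro))) - 2 * Xo %*% t(Ro) +
      outer(rep(1, nrow(Xo)), rowSums(Ro^2))
    for (i in seq_along(rows)) {
      nn <- order(d2[i, ])[seq_len(k)]
      X[rows[i], miss_idx] <- colMeans(R[nn, miss_idx, drop = FALSE])
    }
  }
  for (j in seq_along(columns)) frames[[columns[j]]] <- X[, j]
  frames
}

#' Windowing configuration
#'
#' @param width window length W in minutes (default 30; sessions shorter than
#'   W are excluded).
#' @param stride end-time increment in minutes (default 1).
#' @param semi_seq how semi-sequential columns (ambient temperature, work
#'   intensity, clothing) enter the static vector: their value at the window
#'   end time (`"last"`, default) or their mean over the window (`"mean"`).
#' @return object of class `window_config`.
#' @export
window_config <- function(width = 30, stride = 1,
                          semi_seq = c("last", "mean")) {
  stop_if_not(is_count(width) && width >= 2, "window width must be >= 2")
  stop_if_not(is_count(stride), "stride must be a positive integer")
  structure(list(width = as.integer(width), stride = as.integer(stride),
                 semi_seq = match.arg(semi_seq)),
            class = "window_config")
}

#' Build overlapping history windows
#'
#' Cuts each subject-session into overlapping windows of `width` minutes:
#' the sequential channels (heart rate, skin temperature) carry the previous
#' `width` minutes inclusive of the end time, the static vector carries the
#' demographics plus the semi-sequential values at the end time, and the
#' target is the observed CBT at the end time. Sessions shorter than `width`
#' are dropped; windows whose end-time CBT is missing are skipped. Feature
#' columns must already be complete (run [impute_knn()] first).
#'
#' @param frames imputed session data frame.
#' @param subjects subject table with demographics (`sex` may be character;
#'   it is encoded 0/1).
#' @param config a [window_config()].
#' @return object of class `windowed_dataset`: list with `seq` (array
#'   n x width x 2, channels heart_rate and skin_temp), `static` (matrix
#'   n x 8), `y` (CBT at window end, degC), `provenance` (data frame
#'   `subject_id, session_id, end_time`) and `config`.
#' @export
make_windows <- function(frames, subjects, config = window_config()) {
  stop_if_not(inherits(config, "window_config"),
              "config must come from window_config()")
  seq_cols <- c("heart_rate", "skin_temp")
  semi_cols <- c("ambient_temp", "work_intensity", "clothing")
  stop_if_not(!anyNA(frames[c(seq_cols, semi_cols)]),
              "feature columns contain missing values; impute first")
  demo <- subjects[c("subject_id", "age", "sex", "mass", "height", "bsa")]
  if (is.character(demo$sex) || is.factor(demo$sex))
    demo$sex <- as.numeric(demo$sex == "M")
  W <- config$width
  key <- paste(frames$subject_id, frames$session_id)
  pieces <- split(seq_len(nrow(frames)), key)
  seq_list <- list(); static_list <- list(); y_list <- list(); prov <- list()
  for (piece in pieces) {
    sess <- frames[piece, , drop = FALSE]
    sess <- sess[order(sess$time), , drop = FALSE]
    L <- nrow(sess)
    stop_if_not(all(diff(sess$time) == 1),
                "session %s is not on a 1-minute grid", sess$session_id[1])
    if (L < W) next
    ends <- seq.int(W, L, by = config$stride)
    ends <- ends[!is.na(sess$cbt[ends])]
    if (length(ends) == 0) next
    drow <- demo[match(sess$subject_id[1], demo$subject_id), -1]
    stop_if_not(!anyNA(drow), "subject %s lacks demographics",
                sess$subject_id[1])
    idx <- outer(seq_len(W) - W, ends, "+")          # W x n_windows
    hr <- matrix(sess$heart_rate[idx], nrow = W)
    sk <- matrix(sess$skin_temp[idx], nrow = W)
    semi <- if (config$semi_seq == "last") {
      cbind(sess$ambient_temp[ends], sess$work_intensity[ends],
            sess$clothing[ends])
    } else {
      cbind(colMeans(matrix(sess$ambient_temp[idx], nrow = W)),
            colMeans(matrix(sess$work_intensity[idx], nrow = W)),
            colMeans(matrix(sess$clothing[idx], nrow = W)))
    }
    n <- length(ends)
    seq_arr <- array(0, c(n, W, 2))
    seq_arr[, , 1] <- t(hr); seq_arr[, , 2] <- t(sk)
    seq_list[[length(seq_list) + 1L]] <- seq_arr
    static_list[[length(static_list) + 1L]] <-
      cbind(matrix(rep(as.numeric(drow), each = n), nrow = n), semi)
    y_list[[length(y_list) + 1L]] <- sess$cbt[ends]
    prov[[length(prov) + 1L]] <- data.frame(
      subject_id = sess$subject_id[1], session_id = sess$session_id[1],
      end_time = ends, stringsAsFactors = FALSE)
  }
  if (length(seq_list) == 0) {
    return(structure(list(
      seq = array(0, c(0, W, 2)), static = matrix(0, 0, 8), y = numeric(),
      provenance = data.frame(subject_id = character(),
                              session_id = character(),
                              end_time = integer()),
      config = config), class = "windowed_dataset"))
  }
  n_tot <- sum(vapply(y_list, length, 0L))
  seq_all <- array(0, c(n_tot, W, 2))
  at <- 0L
  for (a in seq_list) {
    n <- dim(a)[1]
    seq_all[at + seq_len(n), , ] <- a
    at <- at + n
  }
  static <- do.call(rbind, static_list)
  colnames(static) <- c("age", "sex", "mass", "height", "bsa", semi_cols)
  structure(list(seq = seq_all, static = static, y = unlist(y_list),
                 provenance = do.call(rbind, prov), config = config),
            class = "windowed_dataset")
}

#' @export
print.windowed_dataset <- function(x, ...) {
  cat(sprintf("Windowed dataset: %d windows of %d min (%d sessions)\n",
              length(x$y), x$config$width,
              length(unique(x$provenance$session_id))))
  invisible(x)
}

#' Subset a windowed dataset by window index
#'
#' @param wd a `windowed_dataset`.
#' @param idx integer or logical index over windows.
#' @return the subsetted `windowed_dataset`.
#' @export
subset_windows <- function(wd, idx) {
  structure(list(seq = wd$seq[idx, , , drop = FALSE],
                 static = wd$static[idx, , drop = FALSE],
                 y = wd$y[idx],
                 provenance = wd$provenance[idx, , drop = FALSE],
                 config = wd$config),
            class = "windowed_dataset")
}
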