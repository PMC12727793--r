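test_that("test carve-out reserves the holdout domain plus k subjects per domain", {
  coh <- generate_cohort(synth_config(n_subjects = 6, seed = 31))
  parts <- carve_test_set(coh, split_config(holdout_domain = "EOD",
                                            k_test_subjects = 4, seed = 2))
  test_subj <- parts$test$subjects
  # every EOD session is in test
  expect_setequal(test_subj$subject_id[test_subj$domain == "EOD"],
                  coh$subjects$subject_id[coh$subjects$domain == "EOD"])
  expect_false("EOD" %in% parts$remainder$subjects$domain)
  # exactly 4 subjects from each non-holdout domain
  other <- table(test_subj$domain[test_subj$domain != "EOD"])
  expect_true(all(other == 4))
  expect_length(other, 5)
  # disjoint outputs
  expect_length(intersect(parts$test$subjects$subject_id,
                          parts$remainder$subjects$subject_id), 0)
  expect_length(intersect(parts$test$sessions$subject_id,
                          parts$remainder$sessions$subject_id), 0)
})

test_that("carve-out errors name an undersized or absent domain", {
  coh <- generate_cohort(synth_config(n_subjects = 3,
                                      domains = c("WFF", "EOD"), seed = 1))
  expect_error(carve_test_set(coh, split_config("EOD", k_test_subjects = 4)),
               "WFF")
  expect_error(carve_test_set(coh, split_config("MINE")), "MINE")
})

test_that("grouped split allocates whole subjects greedily to the ratio targets", {
  # 10 subjects with equal-length sessions -> exact 6/2/2 allocation
  sessions <- data.frame(subject_id = rep(sprintf("s%02d", 1:10), each = 20),
                         session_id = rep(sprintf("s%02d_a", 1:10), each = 20),
                         time = rep(1:20, 10))
  coh <- list(sessions = sessions,
              subjects = data.frame(subject_id = sprintf("s%02d", 1:10)))
  asg <- group_split(coh, c(train = 0.6, validation = 0.2,
                            calibration = 0.2), seed = 5)
  expect_equal(unname(table(asg$split)[c("train", "validation", "calibration")]),
               array(c(6L, 2L, 2L)))
  expect_equal(sort(unique(asg$subject_id)), sort(coh$subjects$subject_id))
  expect_false(anyDuplicated(asg$subject_id) > 0)
  expect_identical(asg, group_split(coh, seed = 5))
  expect_false(identical(asg$split, group_split(coh, seed = 6)$split))
  expect_equal(sum(attr(asg, "achieved")), 1)
})

test_that("scaler is fit on train only, inverts exactly, and guards constants", {
  train <- data.frame(x = c(36, 38), z = c(1, 1))
  expect_warning(st <- fit_scaler(train, c("x", "z")), "constant")
  expect_equal(unname(st$mean[["x"]]), 37)
  expect_equal(unname(st$sd[["x"]]), 1)   # population sd
  scaled <- apply_scaler(st, train)
  expect_equal(scaled$x, c(-1, 1))
  expect_equal(scaled$z, c(0, 0))

  # applying train stats to shifted data leaves a nonzero mean (no refit)
  val <- data.frame(x = c(40, 42), z = c(1, 1))
  expect_gt(abs(mean(apply_scaler(st, val)$x)), 1)

  # round trip
  coh <- small_cohort(seed = 41)
  st2 <- fit_scaler(coh$sessions)
  back <- invert_scaler(st2, apply_scaler(st2, coh$sessions))
  expect_equal(back$heart_rate, coh$sessions$heart_rate, tolerance = 1e-9)
  expect_equal(back$clothing, coh$sessions$clothing, tolerance = 1e-9)
})

test_that("KNN imputation matches an exhaustive nearest-neighbour oracle", {
  cols <- FEATURE_COLS
  set.seed(61)
  ref <- as.data.frame(matrix(rnorm(40 * 5), 40, 5))
  names(ref) <- cols
  frames <- as.data.frame(matrix(rnorm(15 * 5), 15, 5))
  names(frames) <- cols
  holes <- cbind(sample(15, 8, replace = TRUE), sample(5, 8, replace = TRUE))
  for (i in seq_len(nrow(holes))) frames[holes[i, 1], holes[i, 2]] <- NA

  out <- impute_knn(ref, frames, k = 3)
  expect_false(anyNA(out))
  expect_equal(nrow(out), nrow(frames))

  # brute-force oracle: loop over every missing cell
  R <- as.matrix(ref)
  X <- as.matrix(frames)
  for (row in unique(holes[, 1])) {
    miss <- which(is.na(X[row, ]))
    obs <- setdiff(1:5, miss)
    d <- apply(R, 1, function(r) sqrt(sum((r[obs] - X[row, obs])^2)))
    nn <- order(d)[1:3]
    for (j in miss)
      expect_equal(out[row, j], mean(R[nn, j]), tolerance = 1e-12)
  }
})

test_that("KNN imputation leaves complete data untouched and handles exact donors", {
  coh <- small_cohort(seed = 71, missing_rates = c(cbt = 0))
  frames <- coh$sessions
  complete <- frames[complete.cases(frames[FEATURE_COLS]), ]
  expect_identical(impute_knn(complete, complete, k = 5), complete)

  # an identical-except-one-cell donor row is the 1-nearest neighbour
  donor <- complete[1, ]
  query <- donor
  query$heart_rate <- NA
  expect_equal(impute_knn(complete, query, k = 1)$heart_rate,
               donor$heart_rate)

  # a feature absent from every training row is an error
  broken <- complete
  broken$skin_temp <- NA
  expect_error(impute_knn(broken, query), "skin_temp")
})

test_that("windowing emits L - W + 1 windows per retained session and drops short ones", {
  coh <- small_cohort(seed = 81, missing_rates = rates_cbt_only(0))
  frames <- coh$sessions

  clip <- function(frames, sid, len)
    frames[!(frames$session_id == sid & frames$time > len), ]
  sids <- unique(frames$session_id)
  frames <- clip(frames, sids[1], 30)    # exactly one window
  frames <- clip(frames, sids[2], 29)    # dropped
  frames <- clip(frames, sids[3], 45)    # 16 windows

  wd <- make_windows(frames, coh$subjects, window_config(width = 30))
  n_by <- table(wd$provenance$session_id)
  expect_equal(as.integer(n_by[[sids[1]]]), 1L)
  expect_false(sids[2] %in% names(n_by))
  expect_equal(as.integer(n_by[[sids[3]]]), 16L)
  for (sid in setdiff(sids[-2], sids[1:3])) {
    L <- sum(frames$session_id == sid)
    if (L >= 30) expect_equal(as.integer(n_by[[sid]]), L - 30L + 1L)
  }
  # window contents: previous W minutes inclusive of the end time
  i <- which(wd$provenance$session_id == sids[3])[16]
  sess <- frames[frames$session_id == sids[3], ]
  expect_equal(wd$seq[i, , 1], sess$heart_rate[16:45])
  expect_equal(wd$seq[i, , 2], sess$skin_temp[16:45])
  expect_equal(wd$y[i], sess$cbt[45])
  expect_equal(unname(wd$static[i, "ambient_temp"]), sess$ambient_temp[45])
})

test_that("windows with missing end-time CBT are skipped and provenance is injective", {
  coh <- small_cohort(seed = 91, missing_rates = rates_cbt_only(0.1))
  frames <- coh$sessions
  wd <- make_windows(frames, coh$subjects, window_config(width = 30))
  # no emitted window has a missing target
  expect_false(anyNA(wd$y))
  # provenance maps windows 1:1 to (session, end-time)
  key <- paste(wd$provenance$session_id, wd$provenance$end_time)
  expect_false(anyDuplicated(key) > 0)
  # every retained end time has observed CBT in the source frames
  m <- match(paste(frames$session_id, frames$time), key)
  expect_true(all(!is.na(frames$cbt[!is.na(m)])))
})

test_that("preprocessing statistics are leakage-free and reproducible from train rows alone", {
  coh <- generate_cohort(synth_config(n_subjects = 5, seed = 51))
  parts <- carve_test_set(coh, split_config(k_test_subjects = 1, seed = 1))
  asg <- group_split(parts$remainder, seed = 1)
  ids <- split(asg$subject_id, asg$split)
  # no subject in two splits, holdout fully in test
  expect_false(anyDuplicated(asg$subject_id) > 0)
  all_ids <- c(ids$train, ids$validation, ids$calibration,
               parts$test$subjects$subject_id)
  expect_setequal(all_ids, coh$subjects$subject_id)

  train <- coh$sessions[coh$sessions$subject_id %in% ids$train, ]
  st1 <- fit_scaler(train)
  st2 <- fit_scaler(coh$sessions[coh$sessions$subject_id %in% ids$train, ])
  expect_identical(st1, st2)             # bit-for-bit from train rows alone
  # stats differ from full-data stats (so using them would leak)
  expect_false(isTRUE(all.equal(st1$mean, fit_scaler(coh$sessions)$mean)))
})
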