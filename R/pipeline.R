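#' End-to-end pipeline configuration
#'
#' Bundles the per-stage configurations for [run_pipeline()]: simulate (or
#' load) sessions, partition, scale, impute, window, train, conformally
#' calibrate, evaluate against the EKF baseline, and emit alerts.
#'
#' @param synth a [synth_config()] (ignored when `sessions_csv` is given).
#' @param split a [split_config()].
#' @param window a [window_config()].
#' @param model a [model_config()].
#' @param scope a [scope_config()].
#' @param ekf an [ekf_params()].
#' @param alert an [alert_config()].
#' @param model_type `"lstm"` (the hybrid recurrent regressor) or
#'   `"baseline"` (the window-mean linear model, for fast runs).
#' @param knn_k neighbours for imputation.
#' @param sessions_csv,subjects_csv optional paths to user data replacing
#'   the simulator.
#' @param seed run seed; reseeds every stochastic stage so a rerun with the
#'   same configuration reproduces the artifacts.
#' @param out_dir output directory for artifacts (`NULL` = no files
#'   written).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = synth_config(),
                            split = split_config(),
                            window = window_config(),
                            model = model_config(),
                            scope = scope_config(),
                            ekf = ekf_params(),
                            alert = alert_config(),
                            model_type = c("lstm", "baseline"),
                            knn_k = 5,
                            sessions_csv = NULL, subjects_csv = NULL,
                            seed = 1L, out_dir = NULL) {
  structure(list(synth = synth, split = split, window = window,
                 model = model, scope = scope, ekf = ekf, alert = alert,
                 model_type = match.arg(model_type),
                 knn_k = knn_k, sessions_csv = sessions_csv,
                 subjects_csv = subjects_csv, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Demonstration configuration
#'
#' A self-contained synthetic run at study-like scale: a dozen subjects in
#' each of six domains with one to three long sessions each (roughly 5000
#' training windows and 2000+ calibration windows, enough for several
#' strata at the default density), the 3-unit bidirectional recurrent model
#' with its standard hyperparameters, SCOPE at density 1000, and the EKF
#' comparison.
#'
#' @param seed run seed.
#' @param out_dir optional artifact directory.
#' @return a [pipeline_config()].
#' @export
demo_config <- function(seed = 1L, out_dir = NULL) {
  pipeline_config(synth = synth_config(n_subjects = 12,
                                       session_minutes = c(90, 240),
                                       sessions_per_subject = c(2, 3),
                                       seed = seed),
                  split = split_config(seed = seed),
                  model = model_config(seed = seed),
                  seed = seed, out_dir = out_dir)
}

stage <- function(name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
  message(sprintf("[%s] done in %.1fs", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

# scale + impute one split's frames against the train reference
prep_split <- function(frames, scaler, train_scaled, k) {
  impute_knn(train_scaled, apply_scaler(scaler, frames), k = k)
}

#' Run the full pipeline
#'
#' Executes simulate (or load) -> test carve-out -> grouped split ->
#' train-only scaling -> KNN imputation -> windowing -> model training ->
#' SCOPE calibration -> evaluation (multi-level RMSE, coverage curve and
#' AUC, EKF benchmark with burn-in exclusion, paired signed-rank test) ->
#' alert generation. All artifacts are returned; when `out_dir` is set they
#' are also written (split manifest CSV, SCOPE JSON, metric CSV/JSON, alert
#' CSV, run manifest with the configuration and seed).
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with elements `splits`, `scalers`, `model`,
#'   `scope`, `metrics`, `session_metrics`, `alerts`, `coverage`,
#'   `artifacts` (paths, when written).
#' @export
run_pipeline <- function(config = demo_config()) {
  stop_if_not(inherits(config, "pipeline_config"),
              "config must come from pipeline_config()")
  cohort <- stage("simulate", {
    if (!is.null(config$sessions_csv)) {
      list(sessions = read_sessions(config$sessions_csv),
           subjects = read_subjects(config$subjects_csv),
           config = NULL)
    } else generate_cohort(config$synth)
  })

  parts <- stage("partition", {
    carved <- carve_test_set(cohort, config$split)
    assignment <- group_split(carved$remainder, config$split$ratios,
                              seed = config$split$seed)
    ids <- split(assignment$subject_id, assignment$split)
    list(test = carved$test,
         train = cohort_subset(carved$remainder, ids$train),
         validation = cohort_subset(carved$remainder, ids$validation),
         calibration = cohort_subset(carved$remainder, ids$calibration),
         assignment = assignment)
  })

  prep <- stage("scale/impute", {
    demo_cols <- c("age", "mass", "height", "bsa")
    frame_scaler <- fit_scaler(parts$train$sessions, FEATURE_COLUMNS)
    subject_scaler <- fit_scaler(parts$train$subjects, demo_cols)
    train_scaled <- apply_scaler(frame_scaler, parts$train$sessions)
    frames <- lapply(parts[c("train", "validation", "calibration", "test")],
                     function(p) prep_split(p$sessions, frame_scaler,
                                            train_scaled, config$knn_k))
    subjects <- lapply(parts[c("train", "validation", "calibration", "test")],
                       function(p) apply_scaler(subject_scaler, p$subjects))
    list(frames = frames, subjects = subjects,
         scalers = list(frames = frame_scaler, subjects = subject_scaler))
  })

  windows <- stage("window", {
    mapply(function(f, s) make_windows(f, s, config$window),
           prep$frames, prep$subjects, SIMPLIFY = FALSE)
  })

  model <- stage("train", {
    if (config$model_type == "lstm") {
      cbt_lstm(windows$train, windows$validation, config$model)
    } else cbt_baseline(windows$train)
  })

  scope_fit <- stage("calibrate", {
    fit_scope(predict(model, windows$calibration), windows$calibration$y,
              config$scope)
  })

  evaluation <- stage("evaluate", {
    preds <- lapply(windows, function(w) predict(model, w))
    dataset_rmse <- mapply(function(p, w) rmse(p, w$y), preds, windows)
    test_pred <- preds$test
    test_y <- windows$test$y
    sess_tab <- session_rmse_table(test_pred, test_y,
                                   windows$test$provenance,
                                   model_tag = config$model_type)
    curve <- coverage_curve(function(lv)
      predict_interval(scope_fit, test_pred, lv), test_y)
    cov_sigma <- vapply(c(0.6827, 0.9545, 0.9973), function(lv)
      coverage(predict_interval(scope_fit, test_pred, lv), test_y), 0)
    # EKF benchmark on the raw (unscaled) test heart-rate series
    ekf_rows <- list(); ekf_cov <- list()
    raw_test <- parts$test$sessions
    for (sid in unique(raw_test$session_id)) {
      sess <- raw_test[raw_test$session_id == sid, , drop = FALSE]
      sess <- sess[order(sess$time), , drop = FALSE]
      run <- ekf_run(sess$heart_rate, config$ekf)
      keep <- !run$burn_in & !is.na(sess$cbt)
      if (sum(keep) == 0) next
      ekf_rows[[sid]] <- data.frame(subject_id = sess$subject_id[1],
                                    session_id = sid,
                                    pred = run$ct[keep],
                                    obs = sess$cbt[keep],
                                    stringsAsFactors = FALSE)
    }
    ekf_all <- do.call(rbind, ekf_rows)
    ekf_sess <- session_rmse_table(ekf_all$pred, ekf_all$obs,
                                   data.frame(subject_id = ekf_all$subject_id,
                                              session_id = ekf_all$session_id),
                                   model_tag = "ekf")
    # paired comparison on sessions present in both tables
    common <- intersect(sess_tab$session_id, ekf_sess$session_id)
    wtest <- if (length(common) >= 2) {
      paired_signed_rank(
        ekf_sess$rmse[match(common, ekf_sess$session_id)],
        sess_tab$rmse[match(common, sess_tab$session_id)])
    } else NULL
    ekf_rmse <- rmse(ekf_all$pred, ekf_all$obs)
    list(dataset_rmse = dataset_rmse,
         test_rmse = dataset_rmse[["test"]],
         ekf_test_rmse = ekf_rmse,
         pct_reduction_vs_ekf = percent_reduction(ekf_rmse,
                                                  dataset_rmse[["test"]]),
         coverage = stats::setNames(cov_sigma, c("68.27", "95.45", "99.73")),
         coverage_curve = curve,
         coverage_auc = coverage_auc(curve),
         session_table = rbind(sess_tab, ekf_sess),
         signed_rank = wtest)
  })

  alerts <- stage("alert", {
    out <- list()
    prov <- windows$test$provenance
    test_pred <- predict(model, windows$test)
    for (sid in unique(prov$session_id)) {
      sel <- which(prov$session_id == sid)
      iv <- predict_interval(scope_fit, test_pred[sel], config$alert$level)
      iv$time <- prov$end_time[sel]
      iv <- iv[order(iv$time), , drop = FALSE]
      out[[sid]] <- cbind(session_id = sid, stream_alerts(config$alert, iv))
    }
    do.call(rbind, out)
  })

  artifacts <- NULL
  if (!is.null(config$out_dir)) {
    artifacts <- stage("write", {
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      p <- function(f) file.path(config$out_dir, f)
      utils::write.csv(parts$assignment, p("splits.csv"), row.names = FALSE)
      scope_to_json(scope_fit, p("scope.json"))
      utils::write.csv(evaluation$session_table, p("session_metrics.csv"),
                       row.names = FALSE)
      utils::write.csv(alerts, p("alerts.csv"), row.names = FALSE)
      jsonlite::write_json(list(
        seed = config$seed,
        model_type = config$model_type,
        dataset_rmse = as.list(evaluation$dataset_rmse),
        ekf_test_rmse = evaluation$ekf_test_rmse,
        pct_reduction_vs_ekf = evaluation$pct_reduction_vs_ekf,
        coverage = as.list(evaluation$coverage),
        coverage_auc = evaluation$coverage_auc),
        p("metrics.json"), auto_unbox = TRUE, digits = NA)
      cfg_yaml <- p("config.yaml")
      yaml::write_yaml(config_to_list(config), cfg_yaml)
      jsonlite::write_json(list(
        created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
        seed = config$seed,
        config_md5 = unname(tools::md5sum(cfg_yaml)),
        package_version = as.character(utils::packageVersion("heatscope")),
        files = c("splits.csv", "scope.json", "session_metrics.csv",
                  "alerts.csv", "metrics.json", "config.yaml")),
        p("manifest.json"), auto_unbox = TRUE)
      vapply(c("splits.csv", "scope.json", "session_metrics.csv",
               "alerts.csv", "metrics.json", "config.yaml",
               "manifest.json"), p, "")
    })
  }

  invisible(list(splits = parts$assignment, scalers = prep$scalers,
                 windows = windows, model = model, scope = scope_fit,
                 metrics = evaluation[setdiff(names(evaluation),
                                              "session_table")],
                 session_metrics = evaluation$session_table,
                 alerts = alerts, artifacts = artifacts))
}

# plain-list view of a pipeline config for YAML serialisation
config_to_list <- function(config) {
  rapply(unclass(config), identity, how = "replace")
}
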