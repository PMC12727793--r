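test_that("analytic gradients match numerical differentiation", {
  ns <- asNamespace("heatscope")
  set.seed(42)
  B <- 4; W <- 6; p <- 4
  cfg <- model_config(hidden_units = 2, dense_units = 3, dropout = 0,
                      seed = 7)
  mdl <- build_model(cfg, width = W, static_dim = p, y_center = 0.3)
  X <- array(rnorm(B * W * 2), c(B, W, 2))
  S <- matrix(rnorm(B * p), B, p)
  y <- rnorm(B)
  gl <- ns$model_gradients(mdl$params, cfg, X, S, y, NULL)
  analytic <- ns$flatten_params(gl$grads[names(mdl$params)])
  loss_at <- function(par) mean((ns$model_forward(par, cfg, X, S)$yhat - y)^2)

  numeric_ <- c()
  walk <- function(prefix) {
    par <- if (length(prefix)) mdl$params[[prefix]] else mdl$params
    for (nm in names(par)) {
      if (is.list(par[[nm]])) { walk(c(prefix, nm)); next }
      for (j in seq_along(par[[nm]])) {
        bump <- function(h) {
          pp <- mdl$params
          if (length(prefix)) pp[[prefix]][[nm]][j] <- pp[[prefix]][[nm]][j] + h
          else pp[[nm]][j] <- pp[[nm]][j] + h
          loss_at(pp)
        }
        numeric_ <<- c(numeric_, (bump(1e-6) - bump(-1e-6)) / 2e-6)
      }
    }
  }
  walk(character())
  expect_equal(unname(analytic), numeric_, tolerance = 1e-6)
})

test_that("model construction honours the architecture contracts", {
  cfg <- model_config(seed = 9)
  m <- build_model(cfg, width = 30, static_dim = 8)
  expect_s3_class(m, "cbt_lstm")
  expect_false(m$fitted)
  # bidirectional: head consumes 2H + dense units
  expect_length(m$params$w, 2 * 3 + 16)
  m1 <- build_model(model_config(bidirectional = FALSE, seed = 9),
                    width = 30, static_dim = 8)
  expect_length(m1$params$w, 3 + 16)     # recurrent share halves
  expect_null(m1$params$bwd)
  # seeded initialisation is reproducible
  m2 <- build_model(cfg, width = 30, static_dim = 8)
  expect_identical(coef(m), coef(m2))
  expect_error(build_model(cfg, width = 0, static_dim = 8), "width")
})

test_that("training recovers a constant target and stops early on plateaus", {
  wd <- toy_windows(n = 240, width = 5, y = 37.0, seed = 2)
  wd$seq[] <- 0
  wd$static[] <- 0
  train <- subset_windows(wd, 1:180)
  val <- subset_windows(wd, 181:240)
  cfg <- model_config(hidden_units = 2, dense_units = 4, dropout = 0,
                      max_epochs = 20, patience = 3, seed = 4)
  fit <- cbt_lstm(train, val, cfg)
  expect_true(all(abs(predict(fit, val) - 37.0) < 0.05))
  # constant data: validation loss cannot improve after the optimum
  expect_lt(nrow(fit$history), cfg$max_epochs)
  expect_equal(fit$best_epoch, which.min(fit$history$val_loss))
})

test_that("training history and predictions are deterministic per seed", {
  wd <- toy_windows(n = 150, width = 5, seed = 3)
  # give the features real signal so training does something
  wd$y <- 37 + 0.5 * apply(wd$seq[, , 1], 1, mean) + 0.2 * wd$static[, 1]
  train <- subset_windows(wd, 1:100)
  val <- subset_windows(wd, 101:150)
  cfg <- model_config(hidden_units = 2, dense_units = 4, max_epochs = 4,
                      seed = 11)
  f1 <- cbt_lstm(train, val, cfg)
  f2 <- cbt_lstm(train, val, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(coef(f1), coef(f2))
  expect_equal(nrow(f1$history), 4)      # history length equals epochs run

  # inference determinism and order preservation (dropout off at predict)
  p1 <- predict(f1, val)
  expect_identical(p1, predict(f1, val))
  expect_length(p1, 50)
  dup <- subset_windows(val, c(1, 1))
  pd <- predict(f1, dup)
  expect_identical(pd[1], pd[2])

  # shape mismatch is an error
  expect_error(predict(f1, toy_windows(n = 5, width = 7)), "shape")
})

test_that("the hybrid model learns synthetic physiology to clinical accuracy", {
  # small cohort, baseline-vs-LSTM on held-out subjects
  # hetero_slope 0: the observed-CBT noise floor stays at 0.1 degC, so the
  # residual measures what the network learned rather than sensor noise
  coh <- generate_cohort(synth_config(n_subjects = 6,
                                      domains = c("WFF", "FACT"),
                                      missing_rates = rates_cbt_only(0),
                                      hetero_slope = 0,
                                      seed = 13))
  scaler <- fit_scaler(coh$sessions)
  frames <- apply_scaler(scaler, coh$sessions)
  dscaler <- fit_scaler(coh$subjects, c("age", "mass", "height", "bsa"))
  subjects <- apply_scaler(dscaler, coh$subjects)
  wd <- make_windows(frames, subjects)
  ids <- unique(wd$provenance$subject_id)
  tr <- wd$provenance$subject_id %in% ids[1:8]
  va <- wd$provenance$subject_id %in% ids[9:10]
  te <- wd$provenance$subject_id %in% ids[11:12]
  fit <- cbt_lstm(subset_windows(wd, tr), subset_windows(wd, va),
                  model_config(max_epochs = 35, seed = 5))
  test_wd <- subset_windows(wd, te)
  expect_lt(rmse(predict(fit, test_wd), test_wd$y), 0.5)

  # the trivial baseline regressor fits the same interface
  base <- cbt_baseline(subset_windows(wd, tr))
  pb <- predict(base, test_wd)
  expect_length(pb, sum(te))
  expect_true(all(is.finite(pb)))
})
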