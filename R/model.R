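#' Model configuration for the hybrid sequence regressor
#'
#' Hyperparameters of the windowed CBT regressor: a (bidirectional) LSTM over
#' the sequential channels (heart rate, skin temperature), a dense ReLU
#' encoder over the static vector (demographics plus semi-sequential
#' context), concatenation, dropout, and a single linear output unit.
#'
#' @param hidden_units LSTM hidden units per direction (default 3).
#' @param bidirectional process the window in both time directions
#'   (default `TRUE`).
#' @param dense_units width of the static-branch hidden layer (default 16).
#' @param dropout dropout rate on the concatenated feature vector during
#'   training, in \[0, 1) (default 0.5; disabled at prediction time).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param batch_size minibatch size (default 32).
#' @param max_epochs maximum training epochs (default 50).
#' @param patience early-stopping patience in epochs without validation
#'   improvement (default 5).
#' @param restore_best return the parameters of the best validation epoch
#'   (default `TRUE`).
#' @param seed RNG seed controlling initialisation, shuffling and dropout.
#' @return object of class `model_config`.
#' @export
model_config <- function(hidden_units = 3, bidirectional = TRUE,
                         dense_units = 16, dropout = 0.5,
                         learning_rate = 0.001, batch_size = 32,
                         max_epochs = 50, patience = 5,
                         restore_best = TRUE, seed = 1L) {
  stop_if_not(is_count(hidden_units), "hidden_units must be >= 1")
  stop_if_not(dropout >= 0 && dropout < 1, "dropout must lie in [0, 1)")
  stop_if_not(is_count(patience), "patience must be >= 1")
  stop_if_not(is_count(batch_size) && is_count(max_epochs),
              "batch_size and max_epochs must be positive integers")
  structure(list(hidden_units = as.integer(hidden_units),
                 bidirectional = isTRUE(bidirectional),
                 dense_units = as.integer(dense_units), dropout = dropout,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 restore_best = isTRUE(restore_best), seed = seed),
            class = "model_config")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Glorot-uniform matrix
glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

# One LSTM cell bank: gate order i, f, g, o in column blocks of H
init_lstm_dir <- function(n_in, H) {
  b <- rep(0, 4 * H)
  b[H + seq_len(H)] <- 1                 # forget-gate bias at 1
  list(Wx = glorot(n_in, 4 * H), Wh = glorot(H, 4 * H), b = b)
}

#' Build an untrained hybrid model
#'
#' Initialises the parameters of the hybrid regressor for a given window
#' shape. The output bias starts at `y_center` (typically the training-target
#' mean) so the untrained model predicts a sensible constant.
#'
#' @param config a [model_config()].
#' @param width window length in minutes.
#' @param static_dim length of the static feature vector.
#' @param y_center initial output bias, degC (default 37).
#' @return object of class `cbt_lstm` with `fitted = FALSE`.
#' @export
build_model <- function(config = model_config(), width = 30, static_dim = 8,
                        y_center = 37) {
  stop_if_not(is_count(width) && width >= 1, "window width must be positive")
  stop_if_not(is_count(static_dim), "static_dim must be positive")
  H <- config$hidden_units
  with_seed(config$seed, {
    params <- list(fwd = init_lstm_dir(2, H))
    if (config$bidirectional) params$bwd <- init_lstm_dir(2, H)
    concat <- H * (1 + config$bidirectional) + config$dense_units
    params$Ws <- glorot(static_dim, config$dense_units)
    params$bs <- rep(0, config$dense_units)
    params$w <- glorot(concat, 1)
    params$b0 <- y_center
    structure(list(params = params, config = config, width = width,
                   static_dim = static_dim, fitted = FALSE,
                   history = NULL, best_epoch = NA_integer_),
              class = "cbt_lstm")
  })
}

# forward pass of one direction over X (B x W x 2); returns last hidden state
# and the per-step cache needed for backpropagation through time
lstm_forward_dir <- function(X, p, reverse = FALSE) {
  B <- dim(X)[1]; W <- dim(X)[2]; H <- ncol(p$Wh)/4
  ts <- if (reverse) rev(seq_len(W)) else seq_len(W)
  h <- matrix(0, B, H); c_ <- matrix(0, B, H)
  cache <- vector("list", W)
  bmat <- matrix(p$b, B, 4 * H, byrow = TRUE)
  for (s in seq_len(W)) {
    x <- X[, ts[s], , drop = FALSE]; dim(x) <- c(B, dim(X)[3])
    A <- x %*% p$Wx + h %*% p$Wh + bmat
    i <- sigmoid(A[, seq_len(H), drop = FALSE])
    f <- sigmoid(A[, H + seq_len(H), drop = FALSE])
    g <- tanh(A[, 2 * H + seq_len(H), drop = FALSE])
    o <- sigmoid(A[, 3 * H + seq_len(H), drop = FALSE])
    c_prev <- c_; h_prev <- h
    c_ <- f * c_ + i * g
    tc <- tanh(c_)
    h <- o * tc
    cache[[s]] <- list(x = x, i = i, f = f, g = g, o = o,
                       c_prev = c_prev, h_prev = h_prev, tc = tc)
  }
  list(h = h, cache = cache)
}

# gradients of one direction given the gradient at its last hidden state
lstm_backward_dir <- function(dh_last, cache, p) {
  W <- length(cache); H <- ncol(dh_last)
  dWx <- p$Wx * 0; dWh <- p$Wh * 0; db <- p$b * 0
  dh <- dh_last; dc <- dh * 0
  for (s in rev(seq_len(W))) {
    cc <- cache[[s]]
    do_ <- dh * cc$tc
    dc <- dc + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g
    dg <- dc * cc$i
    df <- dc * cc$c_prev
    dA <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do_ * cc$o * (1 - cc$o))
    dWx <- dWx + t(cc$x) %*% dA
    dWh <- dWh + t(cc$h_prev) %*% dA
    db <- db + colSums(dA)
    dh <- dA %*% t(p$Wh)
    dc <- dc * cc$f
  }
  list(Wx = dWx, Wh = dWh, b = db)
}

# full forward pass; drop_mask NULL disables dropout (inference)
model_forward <- function(params, config, Xseq, S, drop_mask = NULL) {
  fwd <- lstm_forward_dir(Xseq, params$fwd, reverse = FALSE)
  parts <- list(fwd$h)
  bwd <- NULL
  if (config$bidirectional) {
    bwd <- lstm_forward_dir(Xseq, params$bwd, reverse = TRUE)
    parts <- c(parts, list(bwd$h))
  }
  Zpre <- S %*% params$Ws + matrix(params$bs, nrow(S), length(params$bs),
                                   byrow = TRUE)
  Z <- pmax(Zpre, 0)
  F_ <- do.call(cbind, c(parts, list(Z)))
  Fd <- if (is.null(drop_mask)) F_ else F_ * drop_mask
  yhat <- drop(Fd %*% params$w) + params$b0
  list(yhat = yhat, F_ = F_, Fd = Fd, Zpre = Zpre, Z = Z,
       fwd = fwd, bwd = bwd)
}

model_gradients <- function(params, config, Xseq, S, y, drop_mask) {
  fw <- model_forward(params, config, Xseq, S, drop_mask)
  B <- length(y); H <- config$hidden_units
  r <- fw$yhat - y
  dyhat <- matrix(2 * r / B, ncol = 1)
  grads <- list()
  grads$w <- t(fw$Fd) %*% dyhat
  grads$b0 <- sum(dyhat)
  dF <- (dyhat %*% t(params$w))
  if (!is.null(drop_mask)) dF <- dF * drop_mask
  off <- 0L
  dhf <- dF[, off + seq_len(H), drop = FALSE]; off <- off + H
  if (config$bidirectional) {
    dhb <- dF[, off + seq_len(H), drop = FALSE]; off <- off + H
  }
  dZ <- dF[, off + seq_len(config$dense_units), drop = FALSE]
  dZpre <- dZ * (fw$Zpre > 0)
  grads$Ws <- t(S) %*% dZpre
  grads$bs <- colSums(dZpre)
  grads$fwd <- lstm_backward_dir(dhf, fw$fwd$cache, params$fwd)
  if (config$bidirectional)
    grads$bwd <- lstm_backward_dir(dhb, fw$bwd$cache, params$bwd)
  list(loss = mean(r^2), grads = grads)
}

# Adam moment update over a nested parameter/gradient tree
adam_update <- function(p, g, m, v, lr_t, b1, b2, eps) {
  for (nm in names(p)) {
    if (is.list(p[[nm]])) {
      res <- adam_update(p[[nm]], g[[nm]], m[[nm]], v[[nm]], lr_t, b1, b2, eps)
      p[[nm]] <- res$p; m[[nm]] <- res$m; v[[nm]] <- res$v
    } else {
      m[[nm]] <- b1 * m[[nm]] + (1 - b1) * g[[nm]]
      v[[nm]] <- b2 * v[[nm]] + (1 - b2) * g[[nm]]^2
      p[[nm]] <- p[[nm]] - lr_t * m[[nm]] / (sqrt(v[[nm]]) + eps)
    }
  }
  list(p = p, m = m, v = v)
}

# flatten parameter trees for coef() and gradient checks
flatten_params <- function(p) {
  unlist(lapply(p, function(e) if (is.list(e)) flatten_params(e) else as.numeric(e)))
}

#' Fit the hybrid CBT regressor
#'
#' Trains the bidirectional-LSTM + dense hybrid by minibatch Adam on mean
#' squared error, shuffling the training windows before every epoch,
#' monitoring validation loss, and stopping early once validation loss has
#' failed to improve for `patience` consecutive epochs. The returned model
#' carries the parameters of the best validation epoch.
#'
#' @param train,validation `windowed_dataset` objects (both non-empty).
#' @param config a [model_config()].
#' @return object of class `cbt_lstm` with elements `params`, `config`,
#'   `history` (per-epoch train/validation loss), `best_epoch`.
#' @examples
#' \donttest{
#' coh <- generate_cohort(synth_config(n_subjects = 3, domains = "FACT",
#'                                     missing_rates = c(cbt = 0)))
#' wd <- make_windows(coh$sessions, coh$subjects)
#' fit <- cbt_lstm(subset_windows(wd, 1:200), subset_windows(wd, 201:260),
#'                 model_config(max_epochs = 3))
#' predict(fit, subset_windows(wd, 261:270))
#' }
#' @export
cbt_lstm <- function(train, validation, config = model_config()) {
  stop_if_not(inherits(train, "windowed_dataset") &&
                inherits(validation, "windowed_dataset"),
              "train and validation must be windowed_dataset objects")
  stop_if_not(length(train$y) > 0 && length(validation$y) > 0,
              "train and validation window sets must be non-empty")
  model <- build_model(config, width = dim(train$seq)[2],
                       static_dim = ncol(train$static),
                       y_center = mean(train$y))
  params <- model$params
  m <- rapply(params, function(x) x * 0, how = "replace")
  v <- m
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  keep <- 1 - config$dropout
  n <- length(train$y)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best_loss <- Inf; best_params <- params; best_epoch <- 0L; stall <- 0L
  with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      order_ <- sample.int(n)
      tr_loss <- 0; n_batches <- 0L
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- order_[start:min(start + config$batch_size - 1L, n)]
        B <- length(idx)
        Xb <- train$seq[idx, , , drop = FALSE]
        Sb <- train$static[idx, , drop = FALSE]
        mask <- if (config$dropout > 0) {
          concat <- length(params$w)
          matrix((stats::runif(B * concat) < keep) / keep, B, concat)
        } else NULL
        gl <- model_gradients(params, config, Xb, Sb, train$y[idx], mask)
        stop_if_not(is.finite(gl$loss),
                    "non-finite training loss at epoch %d; try a smaller learning rate",
                    epoch)
        step <- step + 1L
        lr_t <- config$learning_rate *
          sqrt(1 - b2^step) / (1 - b1^step)
        res <- adam_update(params, gl$grads, m, v, lr_t, b1, b2, eps)
        params <- res$p; m <- res$m; v <- res$v
        tr_loss <- tr_loss + gl$loss
        n_batches <- n_batches + 1L
      }
      val_pred <- model_forward(params, config, validation$seq,
                                validation$static)$yhat
      val_loss <- mean((val_pred - validation$y)^2)
      stop_if_not(is.finite(val_loss),
                  "non-finite validation loss at epoch %d", epoch)
      history <- rbind(history, data.frame(
        epoch = epoch, train_loss = tr_loss / n_batches,
        val_loss = val_loss))
      if (val_loss < best_loss - 1e-12) {
        best_loss <- val_loss; best_params <- params
        best_epoch <- epoch; stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$patience) break
      }
    }
  })
  model$params <- if (config$restore_best) best_params else params
  model$fitted <- TRUE
  model$history <- history
  model$best_epoch <- best_epoch
  model
}

#' @export
print.cbt_lstm <- function(x, ...) {
  dir_ <- if (x$config$bidirectional) "bidirectional" else "unidirectional"
  cat(sprintf("Hybrid CBT regressor: %s LSTM (%d units) + dense(%d)\n",
              dir_, x$config$hidden_units, x$config$dense_units))
  if (isTRUE(x$fitted)) {
    cat(sprintf("  epochs run: %d, best epoch: %d (val MSE %.4f)\n",
                nrow(x$history), x$best_epoch,
                x$history$val_loss[x$best_epoch]))
  } else cat("  (untrained)\n")
  invisible(x)
}

#' @export
coef.cbt_lstm <- function(object, ...) flatten_params(object$params)

#' Predict CBT for a set of windows
#'
#' Inference is deterministic: dropout is disabled and predictions preserve
#' the window order of the input.
#'
#' @param object a fitted `cbt_lstm`.
#' @param newdata a `windowed_dataset` with the same window shape.
#' @param ... unused.
#' @return numeric vector of predicted CBT, degC, one per window.
#' @export
predict.cbt_lstm <- function(object, newdata, ...) {
  stop_if_not(inherits(newdata, "windowed_dataset"),
              "newdata must be a windowed_dataset")
  stop_if_not(dim(newdata$seq)[2] == object$width &&
                ncol(newdata$static) == object$static_dim,
              "window shape %d x %d does not match the trained shape %d x %d",
              dim(newdata$seq)[2], ncol(newdata$static),
              object$width, object$static_dim)
  if (length(newdata$y) == 0) return(numeric())
  model_forward(object$params, object$config, newdata$seq,
                newdata$static)$yhat
}

#' @export
residuals.cbt_lstm <- function(object, newdata, ...) {
  newdata$y - predict(object, newdata)
}

#' Window-mean linear baseline regressor
#'
#' A deliberately simple reference model for fast tests of the conformal
#' layer: ordinary least squares of the end-window CBT on the window means of
#' the two sequential channels plus the static vector.
#'
#' @param train a `windowed_dataset`.
#' @return object of class `cbt_baseline`.
#' @export
cbt_baseline <- function(train) {
  stop_if_not(inherits(train, "windowed_dataset") && length(train$y) > 0,
              "train must be a non-empty windowed_dataset")
  X <- cbind(1, apply(train$seq, c(1, 3), mean), train$static)
  fit <- stats::lm.fit(X, train$y)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  structure(list(beta = beta), class = "cbt_baseline")
}

#' @export
predict.cbt_baseline <- function(object, newdata, ...) {
  X <- cbind(1, apply(newdata$seq, c(1, 3), mean), newdata$static)
  drop(X %*% object$beta)
}
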