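# Sliding-window supervised construction and the hybrid CNN-LSTM (stage 1)
# -> BiGRU residual-rectification (stage 2) stress forecaster, with
# single-stage LSTM/GRU/CNN-LSTM/CNN-GRU baselines.

scale01 <- function(x, lo, hi) if (hi > lo) (x - lo) / (hi - lo) else x * 0
# a constant-target scaler is not invertible; its inverse image is the
# constant itself
unscale01 <- function(x, lo, hi) if (hi > lo) x * (hi - lo) + lo else x * 0 + lo

#' Build supervised sliding-window pairs
#'
#' Each sample is a `window_length` x features block of consecutive rows;
#' the target is the value `horizon_steps` past the window end.  The sample
#' count is `T - window_length - horizon_steps + 1`.  Features and target
#' are min-max scaled to [0, 1]; scaler parameters are retained on the
#' returned object for exact inversion.
#'
#' @param features Numeric matrix (time x features) with column labels,
#'   optionally carrying a `time_h` attribute.
#' @param target Numeric vector aligned with the feature rows.
#' @param window_length Window length in samples (default 15).
#' @param horizon_steps Forecast horizon in samples past the window end
#'   (default 1).
#' @return An object of class `stress_windows`: list with array `x`
#'   (samples x window x features), vector `y` (scaled), `target_time_h`,
#'   `scalers`, `feature_labels`, `window_length`, `horizon_steps`.
#' @export
build_windows <- function(features, target, window_length = 15, horizon_steps = 1) {
  stopifnot(is.matrix(features), nrow(features) == length(target),
            window_length >= 1, horizon_steps >= 1)
  Tn <- nrow(features)
  n <- Tn - window_length - horizon_steps + 1
  if (n < 1) {
    stop("series too short: ", Tn, " rows yield no window of length ",
         window_length, " with horizon ", horizon_steps, call. = FALSE)
  }
  f_lo <- apply(features, 2, min)
  f_hi <- apply(features, 2, max)
  y_lo <- min(target); y_hi <- max(target)
  fs <- sweep(sweep(features, 2, f_lo), 2, pmax(f_hi - f_lo, 1e-300), "/")
  fs[, f_hi == f_lo] <- 0
  ys <- scale01(target, y_lo, y_hi)
  x <- array(0, dim = c(n, window_length, ncol(features)))
  for (i in seq_len(n)) x[i, , ] <- fs[i:(i + window_length - 1), , drop = FALSE]
  tgt_idx <- seq_len(n) + window_length + horizon_steps - 1
  th <- attr(features, "time_h")
  structure(list(
    x = x, y = ys[tgt_idx],
    target_time_h = if (!is.null(th)) th[tgt_idx] else tgt_idx,
    scalers = list(f_lo = f_lo, f_hi = f_hi, y_lo = y_lo, y_hi = y_hi),
    feature_labels = colnames(features),
    window_length = window_length, horizon_steps = horizon_steps
  ), class = "stress_windows")
}

#' Convert a forecast horizon in minutes to window steps
#'
#' @param minutes Horizon in minutes.
#' @param sample_interval_minutes Sampling interval of the series.
#' @return Integer number of steps (must divide evenly and be >= 1).
#' @export
minutes_to_steps <- function(minutes, sample_interval_minutes) {
  steps <- minutes / sample_interval_minutes
  if (abs(steps - round(steps)) > 1e-9 || steps < 1) {
    stop("horizon of ", minutes, " min is not a positive multiple of the ",
         sample_interval_minutes, "-min sampling interval", call. = FALSE)
  }
  as.integer(round(steps))
}

## ---- architectures ---------------------------------------------------------

make_arch <- function(cnn = NULL, rnn = "lstm", layers = 1, hidden = 32,
                      attention = TRUE, dense = 10) {
  list(cnn = cnn, rnn = rnn, layers = layers, hidden = hidden,
       attention = attention, dense = dense)
}

init_net <- function(arch, fin) {
  p <- list()
  rnn_in <- fin
  if (!is.null(arch$cnn)) {
    p$cnn <- conv1d_init(fin, arch$cnn$channels, arch$cnn$kernel)
    rnn_in <- arch$cnn$channels
  }
  width <- if (arch$rnn == "bigru") 2 * arch$hidden else arch$hidden
  p$rnn <- vector("list", arch$layers)
  for (l in seq_len(arch$layers)) {
    fin_l <- if (l == 1) rnn_in else width
    p$rnn[[l]] <- switch(arch$rnn,
                         lstm = lstm_init(fin_l, arch$hidden),
                         gru = gru_init(fin_l, arch$hidden),
                         bigru = bigru_init(fin_l, arch$hidden))
  }
  if (arch$attention) p$att <- attention_init(width, width)
  p$dense <- list()
  din <- width
  for (d in arch$dense) {
    p$dense[[length(p$dense) + 1L]] <- dense_init(din, d)
    din <- d
  }
  p$dense[[length(p$dense) + 1L]] <- dense_init(din, 1)
  p
}

net_forward <- function(params, arch, seq) {
  caches <- list()
  if (!is.null(arch$cnn)) {
    cf <- conv1d_forward(seq, params$cnn)
    caches$cnn <- cf$cache
    seq <- cf$out
  }
  caches$rnn <- vector("list", arch$layers)
  for (l in seq_len(arch$layers)) {
    rf <- switch(arch$rnn,
                 lstm = lstm_forward(seq, params$rnn[[l]]),
                 gru = gru_forward(seq, params$rnn[[l]]),
                 bigru = bigru_forward(seq, params$rnn[[l]]))
    caches$rnn[[l]] <- rf$cache
    seq <- rf$out
  }
  if (arch$attention) {
    af <- attention_forward(seq, params$att)
    caches$att <- af$cache
    ctx <- af$out
  } else {
    ctx <- seq[[length(seq)]]
  }
  caches$Tn <- length(seq)
  caches$dense <- list()
  h <- ctx
  nd <- length(params$dense)
  for (j in seq_len(nd)) {
    act <- if (j < nd) "relu" else "linear"
    df <- dense_forward(h, params$dense[[j]], act)
    caches$dense[[j]] <- df$cache
    h <- df$out
  }
  list(yhat = h, caches = caches)
}

net_backward <- function(params, arch, caches, dy) {
  grads <- list()
  d <- dy
  nd <- length(params$dense)
  gdense <- vector("list", nd)
  for (j in rev(seq_len(nd))) {
    g <- dense_backward(d, caches$dense[[j]])
    gdense[[j]] <- list(W = g$dW, b = g$db)
    d <- g$dx
  }
  if (arch$attention) {
    ga <- attention_backward(d, caches$att)
    dhs <- ga$dhs
    gatt <- list(Wa = ga$dWa, Ua = ga$dUa, ba = ga$dba, v = ga$dv)
  } else {
    Tn <- caches$Tn
    B <- nrow(d)
    zero <- d * 0
    dhs <- c(rep(list(zero), Tn - 1), list(d))
  }
  grnn <- vector("list", arch$layers)
  for (l in rev(seq_len(arch$layers))) {
    g <- switch(arch$rnn,
                lstm = lstm_backward(dhs, caches$rnn[[l]]),
                gru = gru_backward(dhs, caches$rnn[[l]]),
                bigru = bigru_backward(dhs, caches$rnn[[l]]))
    dhs <- g$dseq
    grnn[[l]] <- switch(arch$rnn,
      lstm = list(Wx = g$dWx, Wh = g$dWh, b = g$db),
      gru = list(Wxz = g$dWxz, Wxr = g$dWxr, Wxh = g$dWxh,
                 Whz = g$dWhz, Whr = g$dWhr, U = g$dU,
                 bz = g$dbz, br = g$dbr, bh = g$dbh),
      bigru = list(fwd = list(Wxz = g$fwd$dWxz, Wxr = g$fwd$dWxr,
                              Wxh = g$fwd$dWxh, Whz = g$fwd$dWhz,
                              Whr = g$fwd$dWhr, U = g$fwd$dU,
                              bz = g$fwd$dbz, br = g$fwd$dbr, bh = g$fwd$dbh),
                   bwd = list(Wxz = g$bwd$dWxz, Wxr = g$bwd$dWxr,
                              Wxh = g$bwd$dWxh, Whz = g$bwd$dWhz,
                              Whr = g$bwd$dWhr, U = g$bwd$dU,
                              bz = g$bwd$dbz, br = g$bwd$dbr, bh = g$bwd$dbh)))
  }
  if (!is.null(arch$cnn)) {
    g <- conv1d_backward(dhs, caches$cnn)
    grads$cnn <- list(W = g$dW, b = g$db)
  }
  grads$rnn <- grnn
  if (arch$attention) grads$att <- gatt
  grads$dense <- gdense
  grads
}

seq_from_array <- function(x, idx) {
  Tn <- dim(x)[2]
  lapply(seq_len(Tn), function(t) {
    matrix(x[idx, t, , drop = FALSE], nrow = length(idx))
  })
}

net_predict <- function(params, arch, x, idx = seq_len(dim(x)[1])) {
  as.numeric(net_forward(params, arch, seq_from_array(x, idx))$yhat)
}

# Adam training of one network on scaled windows; returns params + history.
train_net <- function(x, y, arch, epochs = 200, batch_size = 32, lr = 5e-3,
                      patience = 20, seed = 1) {
  n <- dim(x)[1]
  stopifnot(n >= 2, length(y) == n)
  with_seed(seed, {
    params <- init_net(arch, dim(x)[3])
    st <- adam_state(params)
    best <- list(loss = Inf, params = params)
    stall <- 0
    history <- numeric(0)
    for (ep in seq_len(epochs)) {
      perm <- sample(n)
      losses <- numeric(0)
      for (start in seq(1, n, by = batch_size)) {
        idx <- perm[start:min(start + batch_size - 1, n)]
        seq_b <- seq_from_array(x, idx)
        fw <- net_forward(params, arch, seq_b)
        err <- fw$yhat - y[idx]
        loss <- mean(err^2)
        if (!is.finite(loss)) {
          stop("training divergence: NaN loss (arch = ", arch$rnn,
               ", lr = ", lr, ", epoch = ", ep, ")", call. = FALSE)
        }
        losses <- c(losses, loss)
        dy <- 2 * err / length(idx)
        grads <- clip_grads(net_backward(params, arch, fw$caches, dy))
        upd <- adam_update(params, grads, st, lr = lr)
        params <- upd$params
        st <- upd$state
      }
      ep_loss <- mean(losses)
      history <- c(history, ep_loss)
      if (ep_loss < best$loss - 1e-7) {
        best <- list(loss = ep_loss, params = params)
        stall <- 0
      } else {
        stall <- stall + 1
        if (stall >= patience) break
      }
    }
    list(params = best$params, loss_history = history, best_loss = best$loss)
  })
}

## ---- user-facing configuration + training ----------------------------------

#' Hybrid model configuration
#'
#' Defaults follow the monitoring study's printed settings: 2 recurrent
#' layers, LSTM hidden 32 with a 10-unit dense head, BiGRU hidden 32 with a
#' 32-unit dense head and 3 fully connected layers, batch size 32, Adam,
#' sliding window 15, chronological 80/20 train/test split.  The CNN front
#' end (1 layer, kernel 3, 16 channels, ReLU) is the smallest architecture
#' that fulfils the feature-extraction role.
#'
#' @param epochs Training epochs (default 200).
#' @param batch_size Minibatch size (default 32).
#' @param learning_rate Adam learning rate (default 0.005).
#' @param patience Early-stopping patience on the epoch training loss
#'   (default 20).
#' @param train_fraction Chronological training fraction (default 0.8).
#' @param cnn_channels,cnn_kernel CNN front-end size (16, 3).
#' @param lstm_hidden,lstm_layers,lstm_dense Stage-1 LSTM sizes (32, 2, 10).
#' @param bigru_hidden,bigru_layers,bigru_dense Stage-2 BiGRU sizes (32, 2, 32).
#' @param seed Integer seed for reproducible initialization and batching.
#' @return A list of class `hybrid_config`.
#' @export
hybrid_config <- function(epochs = 200, batch_size = 32, learning_rate = 5e-3,
                          patience = 20, train_fraction = 0.8,
                          cnn_channels = 16, cnn_kernel = 3,
                          lstm_hidden = 32, lstm_layers = 2, lstm_dense = 10,
                          bigru_hidden = 32, bigru_layers = 2, bigru_dense = 32,
                          seed = 1L) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0,
            train_fraction > 0, train_fraction < 1)
  structure(as.list(environment()), class = "hybrid_config")
}

stage1_arch <- function(cfg, rnn = "lstm", cnn = TRUE, attention = TRUE) {
  make_arch(
    cnn = if (cnn) list(channels = cfg$cnn_channels, kernel = cfg$cnn_kernel),
    rnn = rnn, layers = cfg$lstm_layers, hidden = cfg$lstm_hidden,
    attention = attention, dense = cfg$lstm_dense)
}

stage2_arch <- function(cfg) {
  make_arch(cnn = NULL, rnn = "bigru", layers = cfg$bigru_layers,
            hidden = cfg$bigru_hidden, attention = TRUE,
            dense = c(cfg$bigru_dense, 8))
}

#' Train the hybrid CNN-LSTM + BiGRU residual-rectification forecaster
#'
#' Stage 1: a 1-D CNN extracts window features and an attention-augmented
#' LSTM predicts the target.  Stage 2: the training-set residuals
#' (truth minus stage-1 prediction, never computed on test data) become the
#' targets of an attention-augmented bidirectional GRU on the same windows.
#' The final prediction is the sum of the two stages, inverse-scaled to the
#' original units.  The train/test split is chronological.
#'
#' @param windows A [build_windows()] object.
#' @param config A [hybrid_config()].
#' @param target_name Label of the forecast target (for reporting).
#' @return An object of class `stress_model` with stage parameters, scalers,
#'   the per-epoch `loss_history` of both stages, held-out `test` indices
#'   and predictions (original scale), and `resid_sd` (validation residual
#'   SD used for 95% bands).
#' @export
train_hybrid <- function(windows, config = hybrid_config(),
                         target_name = "stress") {
  fit_model(windows, config, target_name, architecture = "cnn_lstm_bigru")
}

#' Train a single-stage baseline forecaster
#'
#' `"lstm"` and `"gru"` are plain recurrent baselines (no CNN, no
#' attention); `"cnn_lstm"` and `"cnn_gru"` add the CNN front end and
#' attention (i.e. stage 1 of the hybrid alone).
#'
#' @inheritParams train_hybrid
#' @param architecture One of `"lstm"`, `"gru"`, `"cnn_lstm"`, `"cnn_gru"`.
#' @return A `stress_model`.
#' @export
train_baseline <- function(windows,
                           architecture = c("lstm", "gru", "cnn_lstm", "cnn_gru"),
                           config = hybrid_config(), target_name = "stress") {
  architecture <- match.arg(architecture)
  fit_model(windows, config, target_name, architecture = architecture)
}

fit_model <- function(windows, config, target_name, architecture) {
  stopifnot(inherits(windows, "stress_windows"))
  n <- dim(windows$x)[1]
  n_train <- max(2, floor(config$train_fraction * n))
  if (n_train < 2) stop("need at least 2 training samples", call. = FALSE)
  idx_train <- seq_len(n_train)
  idx_test <- if (n_train < n) (n_train + 1):n else integer(0)
  x_tr <- windows$x[idx_train, , , drop = FALSE]
  y_tr <- windows$y[idx_train]

  arch1 <- switch(architecture,
    cnn_lstm_bigru = stage1_arch(config, "lstm", cnn = TRUE, attention = TRUE),
    cnn_lstm = stage1_arch(config, "lstm", cnn = TRUE, attention = TRUE),
    cnn_gru = stage1_arch(config, "gru", cnn = TRUE, attention = TRUE),
    lstm = stage1_arch(config, "lstm", cnn = FALSE, attention = FALSE),
    gru = stage1_arch(config, "gru", cnn = FALSE, attention = FALSE))
  fit1 <- train_net(x_tr, y_tr, arch1, epochs = config$epochs,
                    batch_size = config$batch_size, lr = config$learning_rate,
                    patience = config$patience, seed = config$seed)

  fit2 <- NULL
  arch2 <- NULL
  if (architecture == "cnn_lstm_bigru") {
    resid_tr <- y_tr - net_predict(fit1$params, arch1, x_tr)
    arch2 <- stage2_arch(config)
    fit2 <- train_net(x_tr, resid_tr, arch2, epochs = config$epochs,
                      batch_size = config$batch_size,
                      lr = config$learning_rate,
                      patience = config$patience, seed = config$seed + 1L)
  }

  model <- structure(list(
    architecture = architecture, target_name = target_name,
    params1 = fit1$params, arch1 = arch1,
    params2 = if (!is.null(fit2)) fit2$params, arch2 = arch2,
    scalers = windows$scalers, feature_labels = windows$feature_labels,
    window_length = windows$window_length,
    horizon_steps = windows$horizon_steps,
    config = config,
    loss_history = list(stage1 = fit1$loss_history,
                        stage2 = if (!is.null(fit2)) fit2$loss_history)
  ), class = "stress_model")

  # Validation residual SD (band width): residuals on the held-out 20%
  # (the chronological validation split); training tail if there is none.
  val_idx <- if (length(idx_test)) idx_test else
    idx_train[idx_train > floor(0.75 * n_train)]
  if (length(val_idx) < 2) val_idx <- idx_train
  pred_val <- predict_scaled(model, windows$x, val_idx)
  resid_val <- unscale01(windows$y[val_idx], windows$scalers$y_lo, windows$scalers$y_hi) -
    unscale01(pred_val, windows$scalers$y_lo, windows$scalers$y_hi)
  model$resid_sd <- sqrt(mean(resid_val^2))   # RMS: robust to residual bias
  if (!is.finite(model$resid_sd)) model$resid_sd <- 0

  if (length(idx_test)) {
    pred_test <- unscale01(predict_scaled(model, windows$x, idx_test),
                           windows$scalers$y_lo, windows$scalers$y_hi)
    truth_test <- unscale01(windows$y[idx_test],
                            windows$scalers$y_lo, windows$scalers$y_hi)
    model$test <- list(index = idx_test, pred = pred_test, truth = truth_test,
                       time_h = windows$target_time_h[idx_test],
                       rmse = sqrt(mean((pred_test - truth_test)^2)))
  }
  model
}

predict_scaled <- function(model, x, idx = seq_len(dim(x)[1])) {
  yh <- net_predict(model$params1, model$arch1, x, idx)
  if (!is.null(model$params2)) {
    yh <- yh + net_predict(model$params2, model$arch2, x, idx)
  }
  yh
}

#' Forecast a stress factor from WBIA features
#'
#' Scales the feature matrix with the scalers stored in the model, rebuilds
#' sliding windows at the model's window length and horizon, and returns
#' point forecasts with Gaussian 95% bands (point +- 1.96 x validation
#' residual SD).
#'
#' @param model A `stress_model` from [train_hybrid()] or [train_baseline()].
#' @param features Feature matrix with the same column labels used in
#'   training (e.g. from [wbia_feature_matrix()], subset to the screened
#'   features plus temperature), optionally with a `time_h` attribute.
#' @param sample_interval_minutes Sampling interval, used only to report the
#'   horizon in minutes.
#' @return A data.frame of class `stress_forecast` with columns `time_h`,
#'   `factor`, `point`, `lower95`, `upper95`, `horizon_min`.
#' @export
forecast_stress <- function(model, features, sample_interval_minutes = 5) {
  stopifnot(inherits(model, "stress_model"))
  if (!identical(colnames(features), model$feature_labels)) {
    stop("feature labels do not match the training features", call. = FALSE)
  }
  sc <- model$scalers
  fs <- sweep(sweep(features, 2, sc$f_lo), 2, pmax(sc$f_hi - sc$f_lo, 1e-300), "/")
  fs[, sc$f_hi == sc$f_lo] <- 0
  Tn <- nrow(fs)
  w <- model$window_length
  h <- model$horizon_steps
  n <- Tn - w - h + 1
  if (n < 1) stop("feature series shorter than one window + horizon", call. = FALSE)
  x <- array(0, dim = c(n, w, ncol(fs)))
  for (i in seq_len(n)) x[i, , ] <- fs[i:(i + w - 1), , drop = FALSE]
  point <- unscale01(predict_scaled(model, x), sc$y_lo, sc$y_hi)
  th <- attr(features, "time_h")
  tgt_idx <- seq_len(n) + w + h - 1
  band <- 1.96 * model$resid_sd
  out <- data.frame(
    time_h = if (!is.null(th)) th[tgt_idx] else tgt_idx,
    factor = model$target_name,
    point = point, lower95 = point - band, upper95 = point + band,
    horizon_min = h * sample_interval_minutes
  )
  class(out) <- c("stress_forecast", "data.frame")
  out
}
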