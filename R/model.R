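# CNN-LSTM window classifier, implemented natively.
#
# Layer stack: conv1d(32, kernel 3) + dropout + ReLU -> conv1d(64, kernel 3)
# + dropout + ReLU -> max-pool(2) -> LSTM(16, last state) -> dense(64, ReLU)
# -> dense(output_units, softmax). Input windows are 30 samples x 13
# channels. Convolutions are im2col matrix products; the LSTM is unrolled
# over the pooled time axis with full backpropagation through time; the
# optimiser is Adam on categorical cross-entropy. Everything is seeded, so
# training is bit-reproducible in a single-threaded session.

#' Classifier configuration
#'
#' The architecture widths follow the published layer stack (32- and
#' 64-filter convolutions, a 16-unit LSTM, a 64-unit dense layer); kernel
#' size, dropout rate, pooling, optimiser settings and epochs are this
#' package's defaults, exposed here. "Dropout with ReLU" is realised as
#' conv -> dropout -> ReLU, in the order the stack lists them. The pooling
#' stage is a max-pool following the 64-filter convolution (pooling itself
#' has no filters).
#'
#' @param conv1_filters,conv2_filters convolution widths.
#' @param kernel_size temporal kernel length in samples.
#' @param dropout_rate dropout probability in `[0, 1)` after each conv.
#' @param pool_size max-pool width over time.
#' @param lstm_units LSTM hidden-state size.
#' @param dense_units width of the penultimate dense layer.
#' @param output_units 2 (non-scratch/scratch) or 3 (non-scratch/scratch/rub,
#'   with rub collapsed into scratch at prediction).
#' @param epochs,batch_size,learning_rate Adam training schedule.
#' @param seed integer seed for initialisation, shuffling and dropout.
#' @return A `model_config` object.
#' @export
model_config <- function(conv1_filters = 32, conv2_filters = 64,
                         kernel_size = 3, dropout_rate = 0.2, pool_size = 2,
                         lstm_units = 16, dense_units = 64, output_units = 2,
                         epochs = 30, batch_size = 32, learning_rate = 1e-3,
                         seed = 1L) {
  counts <- c(conv1_filters, conv2_filters, kernel_size, pool_size,
              lstm_units, dense_units, epochs, batch_size)
  if (any(counts < 1)) stop("all layer sizes and counts must be >= 1")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must lie in [0, 1)")
  if (!output_units %in% c(2L, 3L)) stop("output_units must be 2 or 3")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  structure(list(conv1_filters = as.integer(conv1_filters),
                 conv2_filters = as.integer(conv2_filters),
                 kernel_size = as.integer(kernel_size),
                 dropout_rate = dropout_rate,
                 pool_size = as.integer(pool_size),
                 lstm_units = as.integer(lstm_units),
                 dense_units = as.integer(dense_units),
                 output_units = as.integer(output_units),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 seed = as.integer(seed)),
            class = "model_config")
}

# ---- parameter plumbing -----------------------------------------------------

glorot <- function(nin, nout) {
  matrix(stats::runif(nin * nout, -1, 1) * sqrt(6 / (nin + nout)), nin, nout)
}

init_params <- function(cfg, n_channels = 13L, window_len = 30L) {
  k <- cfg$kernel_size
  t1 <- window_len - k + 1L
  t2 <- t1 - k + 1L
  tp <- t2 %/% cfg$pool_size
  if (tp < 1L) stop("window too short for this architecture")
  u <- cfg$lstm_units
  p <- list(
    Wc1 = glorot(k * n_channels, cfg$conv1_filters),
    bc1 = numeric(cfg$conv1_filters),
    Wc2 = glorot(k * cfg$conv1_filters, cfg$conv2_filters),
    bc2 = numeric(cfg$conv2_filters),
    Wx = glorot(cfg$conv2_filters, 4L * u),
    Wh = glorot(u, 4L * u),
    bl = rep(c(0, 1, 0, 0), each = u),   # forget-gate bias starts at 1
    Wd = glorot(u, cfg$dense_units),
    bd = numeric(cfg$dense_units),
    Wo = glorot(cfg$dense_units, cfg$output_units),
    bo = numeric(cfg$output_units))
  attr(p, "dims") <- list(t1 = t1, t2 = t2, tp = tp,
                          n_channels = n_channels, window_len = window_len)
  p
}

#' Total trainable parameter count of a classifier
#'
#' @param model a `cnn_lstm` model.
#' @return integer parameter count.
#' @export
n_params <- function(model) {
  stopifnot(inherits(model, "cnn_lstm"))
  sum(vapply(model$params, length, integer(1)))
}

#' Build an untrained CNN-LSTM classifier
#'
#' @param cfg a [model_config()].
#' @param n_channels,window_len input geometry (13 processed channels,
#'   30-sample windows).
#' @return An untrained `cnn_lstm` object with seeded initial weights.
#' @export
build_model <- function(cfg = model_config(), n_channels = 13L,
                        window_len = 30L) {
  stopifnot(inherits(cfg, "model_config"))
  params <- with_seed(cfg$seed, function()
    init_params(cfg, n_channels = n_channels, window_len = window_len))
  structure(list(config = cfg, params = params,
                 norm = NULL, history = NULL, trained = FALSE),
            class = "cnn_lstm")
}

#' @export
print.cnn_lstm <- function(x, ...) {
  cat(sprintf("<cnn_lstm> conv(%d)->conv(%d)->pool(%d)->lstm(%d)->dense(%d)->softmax(%d), %d params, %s\n",
              x$config$conv1_filters, x$config$conv2_filters,
              x$config$pool_size, x$config$lstm_units, x$config$dense_units,
              x$config$output_units, n_params(x),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# ---- forward / backward -----------------------------------------------------

# flatten kernel neighbourhoods: (B x T x C) array -> (B*T_out) x (K*C)
im2col <- function(x, k) {
  b <- dim(x)[1L]; tt <- dim(x)[2L]; cc <- dim(x)[3L]
  t_out <- tt - k + 1L
  m <- matrix(0, b * t_out, k * cc)
  for (j in seq_len(k)) {
    sl <- x[, j:(j + t_out - 1L), , drop = FALSE]
    dim(sl) <- c(b * t_out, cc)
    m[, (j - 1L) * cc + seq_len(cc)] <- sl
  }
  m
}

# scatter-add gradient of im2col back onto the input array
col2im <- function(dm, b, tt, cc, k) {
  t_out <- tt - k + 1L
  dx <- array(0, c(b, tt, cc))
  for (j in seq_len(k)) {
    sl <- dm[, (j - 1L) * cc + seq_len(cc), drop = FALSE]
    dim(sl) <- c(b, t_out, cc)
    dx[, j:(j + t_out - 1L), ] <- dx[, j:(j + t_out - 1L), , drop = FALSE] + sl
  }
  dx
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# full forward pass over a batch; keeps caches when training
forward <- function(params, cfg, x, training = FALSE) {
  d <- attr(params, "dims")
  b <- dim(x)[1L]
  keep <- 1 - cfg$dropout_rate

  conv_block <- function(input, w, bias, filters) {
    m <- im2col(input, cfg$kernel_size)
    z <- sweep(m %*% w, 2L, bias, "+")
    mask <- NULL
    if (training && cfg$dropout_rate > 0) {
      mask <- matrix(stats::rbinom(length(z), 1L, keep) / keep,
                     nrow(z), ncol(z))
      z <- z * mask
    }
    a <- pmax(z, 0)
    t_out <- dim(input)[2L] - cfg$kernel_size + 1L
    out <- a
    dim(out) <- c(b, t_out, filters)
    list(m = m, z = z, mask = mask, a = a, out = out)
  }

  c1 <- conv_block(x, params$Wc1, params$bc1, cfg$conv1_filters)
  c2 <- conv_block(c1$out, params$Wc2, params$bc2, cfg$conv2_filters)

  # max-pool over time (width pool_size, stride pool_size; tail dropped)
  ps <- cfg$pool_size
  tp <- d$tp
  pooled <- array(0, c(b, tp, cfg$conv2_filters))
  argmax <- array(0L, c(b, tp, cfg$conv2_filters))
  for (t in seq_len(tp)) {
    block <- c2$out[, (t - 1L) * ps + seq_len(ps), , drop = FALSE]
    # block dims (b, ps, f); collapse to (b*f) rows over the ps pool width
    blk <- aperm(block, c(1L, 3L, 2L))
    dim(blk) <- c(b * cfg$conv2_filters, ps)
    am <- max.col(blk, ties.method = "first")
    pooled[, t, ] <- matrix(blk[cbind(seq_len(nrow(blk)), am)],
                            b, cfg$conv2_filters)
    argmax[, t, ] <- matrix(am, b, cfg$conv2_filters)
  }

  # LSTM over the pooled time axis, gates ordered [input, forget, cell, output]
  u <- cfg$lstm_units
  h <- matrix(0, b, u); cc <- matrix(0, b, u)
  cache <- if (training) vector("list", tp) else NULL
  for (t in seq_len(tp)) {
    xt <- matrix(pooled[, t, ], b, cfg$conv2_filters)
    z <- sweep(xt %*% params$Wx + h %*% params$Wh, 2L, params$bl, "+")
    ig <- sigmoid(z[, seq_len(u), drop = FALSE])
    fg <- sigmoid(z[, u + seq_len(u), drop = FALSE])
    gg <- tanh(z[, 2L * u + seq_len(u), drop = FALSE])
    og <- sigmoid(z[, 3L * u + seq_len(u), drop = FALSE])
    c_new <- fg * cc + ig * gg
    h_new <- og * tanh(c_new)
    if (training)
      cache[[t]] <- list(xt = xt, h_prev = h, c_prev = cc, i = ig, f = fg,
                         g = gg, o = og, c = c_new)
    h <- h_new; cc <- c_new
  }

  zd <- sweep(h %*% params$Wd, 2L, params$bd, "+")
  ad <- pmax(zd, 0)
  zo <- sweep(ad %*% params$Wo, 2L, params$bo, "+")
  zo <- zo - apply(zo, 1L, max)
  ez <- exp(zo)
  prob <- ez / rowSums(ez)

  out <- list(prob = prob)
  if (training)
    out <- c(out, list(x = x, c1 = c1, c2 = c2, pooled = pooled,
                       argmax = argmax, lstm = cache, h = h, zd = zd, ad = ad))
  out
}

backward <- function(params, cfg, fw, y_onehot) {
  d <- attr(params, "dims")
  b <- nrow(fw$prob)
  u <- cfg$lstm_units
  g <- list()

  dzo <- (fw$prob - y_onehot) / b
  g$Wo <- t(fw$ad) %*% dzo
  g$bo <- colSums(dzo)
  dad <- dzo %*% t(params$Wo)
  dzd <- dad * (fw$zd > 0)
  g$Wd <- t(fw$h) %*% dzd
  g$bd <- colSums(dzd)
  dh <- dzd %*% t(params$Wd)

  # BPTT
  tp <- d$tp
  dc <- matrix(0, b, u)
  g$Wx <- matrix(0, nrow(params$Wx), ncol(params$Wx))
  g$Wh <- matrix(0, nrow(params$Wh), ncol(params$Wh))
  g$bl <- numeric(length(params$bl))
  dpooled <- array(0, dim(fw$pooled))
  for (t in rev(seq_len(tp))) {
    cc <- fw$lstm[[t]]
    tanh_c <- tanh(cc$c)
    do <- dh * tanh_c * cc$o * (1 - cc$o)
    dct <- dc + dh * cc$o * (1 - tanh_c^2)
    di <- dct * cc$g * cc$i * (1 - cc$i)
    df <- dct * cc$c_prev * cc$f * (1 - cc$f)
    dg <- dct * cc$i * (1 - cc$g^2)
    dz <- cbind(di, df, dg, do)
    g$Wx <- g$Wx + t(cc$xt) %*% dz
    g$Wh <- g$Wh + t(cc$h_prev) %*% dz
    g$bl <- g$bl + colSums(dz)
    dpooled[, t, ] <- dz %*% t(params$Wx)
    dh <- dz %*% t(params$Wh)
    dc <- dct * cc$f
  }

  # unpool: route gradient to each window's argmax position
  ps <- cfg$pool_size
  f2 <- cfg$conv2_filters
  dconv2 <- array(0, c(b, d$t2, f2))
  for (t in seq_len(tp)) {
    am <- fw$argmax[, t, ]                       # b x f2, values in 1..ps
    dp <- matrix(dpooled[, t, ], b, f2)
    for (j in seq_len(ps)) {
      sel <- am == j
      if (any(sel)) {
        sl <- matrix(0, b, f2)
        sl[sel] <- dp[sel]
        dconv2[, (t - 1L) * ps + j, ] <- dconv2[, (t - 1L) * ps + j, ] + sl
      }
    }
  }

  conv_back <- function(cache, dout_arr, w, input_dims) {
    da <- dout_arr
    dim(da) <- c(dim(dout_arr)[1L] * dim(dout_arr)[2L], dim(dout_arr)[3L])
    dz <- da * (cache$z > 0)
    if (!is.null(cache$mask)) dz <- dz * cache$mask
    list(W = t(cache$m) %*% dz, b = colSums(dz),
         dx = col2im(dz %*% t(w), input_dims[1L], input_dims[2L],
                     input_dims[3L], cfg$kernel_size))
  }

  cb2 <- conv_back(fw$c2, dconv2, params$Wc2,
                   c(b, d$t1, cfg$conv1_filters))
  g$Wc2 <- cb2$W; g$bc2 <- cb2$b
  cb1 <- conv_back(fw$c1, cb2$dx, params$Wc1,
                   c(b, d$window_len, d$n_channels))
  g$Wc1 <- cb1$W; g$bc1 <- cb1$b
  g
}

cross_entropy <- function(prob, y_onehot) {
  -mean(log(pmax(rowSums(prob * y_onehot), 1e-12)))
}

# ---- normalisation ----------------------------------------------------------

fit_norm <- function(windows) {
  ch <- dim(windows)[3L]
  mu <- numeric(ch); sd <- numeric(ch)
  for (c0 in seq_len(ch)) {
    v <- windows[, , c0]
    mu[c0] <- mean(v)
    sd[c0] <- max(stats::sd(v), 1e-6)
  }
  list(mean = mu, sd = sd)
}

apply_norm <- function(windows, norm) {
  for (c0 in seq_len(dim(windows)[3L]))
    windows[, , c0] <- (windows[, , c0] - norm$mean[c0]) / norm$sd[c0]
  windows
}

# ---- training / prediction --------------------------------------------------

#' Train a CNN-LSTM classifier on a window set
#'
#' Per-channel normalisation statistics (mean, SD over all training samples)
#' are fitted on the training windows only and stored with the model;
#' prediction always reuses them, never statistics of the data being
#' scored. Training is mini-batch Adam on categorical cross-entropy, fully
#' seeded (initialisation, shuffling, dropout).
#'
#' @param model an untrained model from [build_model()].
#' @param train_set a [window_set()] containing both classes.
#' @param class_labels optional integer vector overriding
#'   `train_set$labels` with classes `0..output_units-1` (used by the
#'   3-class non-scratch/scratch/rub variant).
#' @param verbose print per-epoch loss/accuracy.
#' @return A trained `cnn_lstm` with `norm` statistics and a `history`
#'   data frame (one row per epoch: loss, accuracy).
#' @export
train_model <- function(model, train_set, class_labels = NULL,
                        verbose = FALSE) {
  stopifnot(inherits(model, "cnn_lstm"), inherits(train_set, "window_set"))
  cfg <- model$config
  y <- if (is.null(class_labels)) train_set$labels else as.integer(class_labels)
  if (length(y) != n_windows(train_set))
    stop("one class label per window required")
  if (any(y < 0L | y >= cfg$output_units))
    stop("class labels must lie in 0..output_units-1")
  if (length(unique(y)) < 2L)
    stop("training set must contain at least two classes")

  norm <- fit_norm(train_set$windows)
  x_all <- apply_norm(train_set$windows, norm)
  n <- dim(x_all)[1L]
  y1 <- matrix(0, n, cfg$output_units)
  y1[cbind(seq_len(n), y + 1L)] <- 1

  params <- model$params
  adam_m <- lapply(params, function(p) p * 0)
  adam_v <- lapply(params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        accuracy = numeric(0))

  run <- function() {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_hits <- 0
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        xb <- x_all[idx, , , drop = FALSE]
        yb <- y1[idx, , drop = FALSE]
        fw <- forward(params, cfg, xb, training = TRUE)
        gr <- backward(params, cfg, fw, yb)
        step <<- step + 1L
        for (nm in names(params)) {
          adam_m[[nm]] <<- beta1 * adam_m[[nm]] + (1 - beta1) * gr[[nm]]
          adam_v[[nm]] <<- beta2 * adam_v[[nm]] + (1 - beta2) * gr[[nm]]^2
          mhat <- adam_m[[nm]] / (1 - beta1^step)
          vhat <- adam_v[[nm]] / (1 - beta2^step)
          params[[nm]] <<- params[[nm]] -
            cfg$learning_rate * mhat / (sqrt(vhat) + eps)
        }
        ep_loss <- ep_loss + cross_entropy(fw$prob, yb) * length(idx)
        ep_hits <- ep_hits +
          sum(max.col(fw$prob, ties.method = "first") == y[idx] + 1L)
      }
      history[nrow(history) + 1L, ] <<- list(epoch, ep_loss / n, ep_hits / n)
      if (verbose)
        message(sprintf("epoch %d/%d loss %.4f acc %.3f", epoch, cfg$epochs,
                        ep_loss / n, ep_hits / n))
    }
  }
  with_seed(cfg$seed + 1L, run)

  model$params <- params
  model$norm <- norm
  model$history <- history
  model$trained <- TRUE
  model
}

#' Predict window labels with a trained classifier
#'
#' Returns binary scratch labels: the argmax class, with the 3-class
#' variant's rub class collapsed into scratch.
#'
#' @param object a trained `cnn_lstm`.
#' @param set a [window_set()] with matching window geometry.
#' @param type `"class"` for binary labels, `"prob"` for the softmax matrix.
#' @param ... unused.
#' @return integer vector of 0/1, or a probability matrix.
#' @export
predict.cnn_lstm <- function(object, set, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  stopifnot(inherits(set, "window_set"))
  if (!object$trained) stop("model has not been trained")
  d <- attr(object$params, "dims")
  if (dim(set$windows)[2L] != d$window_len ||
      dim(set$windows)[3L] != d$n_channels)
    stop("window geometry does not match the trained model")
  if (n_windows(set) == 0L) {
    return(if (type == "class") integer(0)
           else matrix(0, 0L, object$config$output_units))
  }
  x <- apply_norm(set$windows, object$norm)
  prob <- forward(object$params, object$config, x, training = FALSE)$prob
  if (type == "prob") return(prob)
  cls <- max.col(prob, ties.method = "first") - 1L
  as.integer(cls >= 1L)   # collapse rub (2) into scratch (1)
}

# ---- deterministic rule baseline -------------------------------------------

#' Spectral rule baseline detector
#'
#' A training-free reference detector used to cross-check the network: a
#' window counts as scratch if any fast-path stretch channel carries enough
#' 3-8 Hz band power (finger-dominant signature), or if an accelerometer
#' channel does while at least three fingers are mostly bent (arm-dominant
#' signature). Band powers are periodogram sums over the window.
#'
#' @param set a [window_set()].
#' @param fs sampling rate of the windows in Hz.
#' @param band scratch frequency band in Hz.
#' @param stretch_power_thr,accel_power_thr band-power thresholds
#'   (milliohm^2 and g^2 periodogram units); defaults sit an order of
#'   magnitude above noise-floor band power and an order below a full-bout
#'   scratch oscillation.
#' @param bend_channels_min minimum count of mostly-bent fingers for the
#'   arm-dominant rule.
#' @return integer vector of 0/1 window labels.
#' @export
rule_baseline <- function(set, fs = 20, band = c(3, 8),
                          stretch_power_thr = 100, accel_power_thr = 0.05,
                          bend_channels_min = 3) {
  stopifnot(inherits(set, "window_set"))
  w <- n_windows(set)
  out <- integer(w)
  for (k in seq_len(w)) {
    win <- set$windows[k, , ]
    sp <- vapply(1:5, function(j) band_power(win[, j], fs, band[1], band[2]),
                 numeric(1))
    ap <- vapply(6:8, function(j) band_power(win[, j], fs, band[1], band[2]),
                 numeric(1))
    bent <- sum(colMeans(win[, 9:13, drop = FALSE]) > 0.5)
    out[k] <- as.integer(max(sp) >= stretch_power_thr ||
                           (max(ap) >= accel_power_thr &&
                              bent >= bend_channels_min))
  }
  out
}

# ---- persistence ------------------------------------------------------------

#' Save / load a trained classifier as portable JSON
#'
#' The file stores the configuration, per-channel normalisation statistics,
#' training history and all weight arrays as plain JSON, so a model survives
#' R sessions and platforms.
#'
#' @param model a `cnn_lstm`.
#' @param path output `.json` path.
#' @return `path` (save) or the restored `cnn_lstm` (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "cnn_lstm"))
  dims <- attr(model$params, "dims")
  payload <- list(
    config = unclass(model$config),
    dims = dims,
    trained = model$trained,
    norm = model$norm,
    history = model$history,
    params = lapply(model$params, function(p)
      list(dim = if (is.matrix(p)) dim(p) else length(p),
           data = as.numeric(p))))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(model_config, payload$config)
  params <- lapply(payload$params, function(p) {
    if (length(p$dim) == 2L) matrix(p$data, p$dim[1L], p$dim[2L])
    else as.numeric(p$data)
  })
  attr(params, "dims") <- as.list(payload$dims)
  structure(list(config = cfg, params = params,
                 norm = payload$norm,
                 history = as.data.frame(payload$history),
                 trained = isTRUE(payload$trained)),
            class = "cnn_lstm")
}
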