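# two linearly separated synthetic classes straight in window space:
# class 1 carries a 5 Hz oscillation on the first channels, class 0 is noise
separable_windows <- function(n_per_class = 40, seed = 1) {
  withr::with_seed(seed, {
    w <- 2 * n_per_class
    arr <- array(rnorm(w * 30 * 13, sd = 0.5), c(w, 30, 13))
    t <- (0:29) / 20
    for (k in seq_len(n_per_class)) {
      for (j in 1:3)
        arr[k, , j] <- arr[k, , j] +
          10 * sin(2 * pi * 5 * t + runif(1, 0, 2 * pi))
      arr[k, , 9:13] <- 1
    }
    window_set(arr, labels = rep(c(1L, 0L), each = n_per_class),
               starts = seq_len(w))
  })
}

test_that("softmax outputs are probabilities for both output widths", {
  for (u in c(2L, 3L)) {
    m <- build_model(model_config(output_units = u, seed = 2L))
    x <- array(rnorm(5 * 30 * 13), c(5, 30, 13))
    prob <- sigmaglove:::forward(m$params, m$config, x)$prob
    expect_identical(dim(prob), c(5L, u))
    expect_equal(rowSums(prob), rep(1, 5), tolerance = 1e-9)
    expect_true(all(prob >= 0))
  }
})

test_that("the parameter count follows the layer algebra", {
  cfg <- model_config()
  m <- build_model(cfg)
  k <- cfg$kernel_size
  expected <- (k * 13 + 1) * cfg$conv1_filters +
    (k * cfg$conv1_filters + 1) * cfg$conv2_filters +
    4 * cfg$lstm_units * (cfg$conv2_filters + cfg$lstm_units + 1) +
    (cfg$lstm_units + 1) * cfg$dense_units +
    (cfg$dense_units + 1) * cfg$output_units
  expect_identical(n_params(m), as.integer(expected))
})

test_that("analytic gradients match numeric gradients through the whole stack", {
  cfg <- tiny_model_config()
  m <- build_model(cfg, n_channels = 4L, window_len = 12L)
  params <- m$params
  withr::with_seed(5, {
    x <- array(rnorm(3 * 12 * 4), c(3, 12, 4))
    y <- matrix(0, 3, 2); y[cbind(1:3, c(1, 2, 1))] <- 1
  })
  loss_at <- function(p) {
    fw <- sigmaglove:::forward(p, cfg, x, training = FALSE)
    sigmaglove:::cross_entropy(fw$prob, y)
  }
  fw <- sigmaglove:::forward(params, cfg, x, training = TRUE)
  gr <- sigmaglove:::backward(params, cfg, fw, y)
  eps <- 1e-6
  withr::with_seed(6, {
    for (nm in names(params)) {
      for (probe in seq_len(3)) {
        i <- sample(length(params[[nm]]), 1)
        p_hi <- params; p_hi[[nm]][i] <- p_hi[[nm]][i] + eps
        p_lo <- params; p_lo[[nm]][i] <- p_lo[[nm]][i] - eps
        numeric_grad <- (loss_at(p_hi) - loss_at(p_lo)) / (2 * eps)
        expect_equal(gr[[nm]][i], numeric_grad, tolerance = 1e-4,
                     label = sprintf("d loss / d %s[%d]", nm, i))
      }
    }
  })
})

test_that("training is deterministic given the seed and records its history", {
  ws <- separable_windows(20, seed = 3)
  cfg <- tiny_model_config()
  t1 <- train_model(build_model(cfg), ws)
  t2 <- train_model(build_model(cfg), ws)
  expect_identical(t1$history, t2$history)
  expect_identical(t1$params, t2$params)
  expect_identical(nrow(t1$history), cfg$epochs)
})

test_that("a high-SNR separable corpus trains to high accuracy", {
  ws <- separable_windows(40, seed = 4)
  cfg <- model_config(epochs = 8, seed = 9L)
  tm <- train_model(build_model(cfg), ws)
  expect_gte(tail(tm$history$accuracy, 1), 0.95)
  expect_true(all(predict(tm, ws) %in% c(0L, 1L)))
})

test_that("single-class training sets are refused", {
  ws <- separable_windows(10, seed = 5)
  only1 <- subset_windows(ws, ws$labels == 1L)
  expect_error(train_model(build_model(tiny_model_config()), only1),
               "two classes")
})

test_that("normalisation statistics come from the training windows only", {
  ws <- separable_windows(20, seed = 6)
  shifted <- ws
  shifted$windows <- shifted$windows + 100
  tm <- train_model(build_model(tiny_model_config()), shifted)
  expect_equal(tm$norm$mean, sigmaglove:::fit_norm(shifted$windows)$mean)
  norm_before <- tm$norm
  invisible(predict(tm, ws))
  expect_identical(tm$norm, norm_before)   # scoring never refits statistics
})

test_that("predictions are invariant to window order", {
  ws <- separable_windows(15, seed = 7)
  tm <- train_model(build_model(tiny_model_config()), ws)
  perm <- rev(seq_len(n_windows(ws)))
  expect_identical(predict(tm, ws)[perm],
                   predict(tm, subset_windows(ws, perm)))
})

test_that("the three-class variant collapses rub into scratch at prediction", {
  ws <- separable_windows(15, seed = 8)
  # synthesise a third class by flipping sign on the marker channels
  cls <- ws$labels
  cls[seq_len(5)] <- 2L
  cfg <- tiny_model_config(output_units = 3)
  tm <- train_model(build_model(cfg), ws, class_labels = cls)
  prob <- predict(tm, ws, type = "prob")
  expect_identical(ncol(prob), 3L)
  expect_true(all(predict(tm, ws) %in% c(0L, 1L)))
})

test_that("models survive a save/load round trip with identical predictions", {
  ws <- separable_windows(15, seed = 9)
  tm <- train_model(build_model(tiny_model_config()), ws)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(tm, path)
  back <- load_model(path)
  expect_identical(predict(back, ws), predict(tm, ws))
  expect_equal(back$params$Wc1, tm$params$Wc1, tolerance = 1e-12)
})

test_that("the rule baseline flags scratch-band energy and stays silent on zeros", {
  zero <- window_set(array(0, c(1, 30, 13)), 0L, 1L)
  expect_identical(rule_baseline(zero), 0L)
  a <- generate_action(action_spec("scratch_finger"), synth_config(seed = 23L))
  pc <- process_recording(a$recording)
  sl <- extract_center(pc, a$labels)
  ws <- make_windows(sl$processed, sl$labels)
  expect_true(all(rule_baseline(ws) == 1L))
})
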