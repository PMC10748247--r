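# Shared fixture builders. Everything is generated in code at test time.

# a small seeded random recording for round-trip and property tests
random_recording <- function(n = 50, seed = 1) {
  withr::with_seed(seed, sensor_recording(
    stretch = matrix(rnorm(n * 5, sd = 10), n, 5),
    accel = matrix(rnorm(n * 3, sd = 0.5), n, 3),
    subject_id = "fixture"))
}

# processed channels wrapping an arbitrary 13-column matrix
processed_from_matrix <- function(mat) {
  processed_channels(filtered = mat[, 1:8, drop = FALSE],
                     bend = mat[, 9:13, drop = FALSE])
}

# uniform-label processed bout of n samples with deterministic content
ramp_processed <- function(n, label = 0L) {
  mat <- cbind(matrix(seq_len(n * 8), n, 8), matrix(0L, n, 5))
  list(processed = processed_from_matrix(mat),
       labels = label_track(rep(label, n)))
}

# steady-state amplitude of a sinusoid in y, by least-squares regression
# (robust to coarse sampling, unlike peak-picking)
sine_amplitude <- function(y, freq, fs, settle_s = 20) {
  n <- length(y)
  idx <- (settle_s * fs):n
  t <- (idx - 1) / fs
  fit <- stats::lm(y[idx] ~ sin(2 * pi * freq * t) + cos(2 * pi * freq * t))
  sqrt(sum(stats::coef(fit)[2:3]^2))
}

# frequency of the periodogram argmax
dominant_freq <- function(x, fs) {
  n <- length(x)
  spec <- Mod(stats::fft(x - mean(x)))^2
  half <- 2:(floor(n / 2) + 1)
  (half[which.max(spec[half])] - 1) * fs / n
}

tiny_model_config <- function(...) {
  model_config(conv1_filters = 4, conv2_filters = 6, lstm_units = 5,
               dense_units = 8, epochs = 3, batch_size = 8,
               dropout_rate = 0, seed = 11L, ...)
}
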