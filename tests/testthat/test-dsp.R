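test_that("the fast-path high-pass rejects DC after its transient", {
  # causal 4th-order start-up transient decays below 1e-3 within ~6 s
  y <- highpass_butterworth(rep(7, 400), cutoff_hz = 0.5, order = 4, fs = 20)
  expect_lt(max(abs(y[121:400])), 1e-3 * 7)
})

test_that("gain at the cutoff is -3 dB and the scratch band passes at unit gain", {
  fs <- 20
  t <- seq(0, 120, by = 1 / fs)
  for (case in list(list(f = 0.5, expect = 1 / sqrt(2)),
                    list(f = 5, expect = 1),
                    list(f = 3, expect = 1))) {
    x <- sin(2 * pi * case$f * t)
    y <- highpass_butterworth(x, cutoff_hz = 0.5, order = 4, fs = fs)
    amp <- sine_amplitude(y, case$f, fs)
    expect_equal(amp, case$expect, tolerance = 0.01)
  }
})

test_that("cutoffs at or beyond Nyquist are rejected", {
  expect_error(highpass_butterworth(rnorm(10), 10, fs = 20), "cutoff")
  expect_error(highpass_butterworth(rnorm(10), -1, fs = 20), "cutoff")
})

test_that("the strided moving average holds window means at full rate", {
  expect_equal(moving_average(rep(3.5, 100)), rep(3.5, 100))
  x <- c(rep(0, 20), rep(1, 20))
  expect_equal(moving_average(x, window = 20, step = 20),
               c(rep(0, 20), rep(1, 20)))
  # length contract across geometries
  for (n in c(1, 19, 30, 45, 100)) {
    expect_length(moving_average(rnorm(n), window = 30, step = 20), n)
  }
  # window longer than the series degenerates to the global mean
  x <- 1:10
  expect_equal(moving_average(x, window = 50, step = 20), rep(5.5, 10))
})

test_that("bend state thresholds magnitude with ties counting as bent", {
  expect_identical(bend_state(c(12, -12)), c(1L, 1L))
  expect_identical(bend_state(c(0, 9.99)), c(0L, 0L))
  expect_identical(bend_state(10), 1L)
})

test_that("filter stages are linear", {
  withr::with_seed(31, {
    x <- rnorm(200); y <- rnorm(200)
    for (fn in list(function(v) highpass_butterworth(v, 0.5, 4, 20),
                    function(v) highpass_butterworth(v, 0.03, 4, 20),
                    function(v) moving_average(v))) {
      expect_equal(fn(2.5 * x - 1.3 * y), 2.5 * fn(x) - 1.3 * fn(y),
                   tolerance = 1e-9)
    }
  })
})

test_that("an all-zero recording processes to 13 all-zero channels", {
  rec <- sensor_recording(matrix(0, 100, 5), matrix(0, 100, 3))
  pc <- process_recording(rec)
  mat <- processed_matrix(pc)
  expect_identical(dim(mat), c(100L, 13L))
  expect_true(all(mat == 0))
  expect_identical(colnames(mat),
                   c("d1f", "d2f", "d3f", "d4f", "d5f", "axf", "ayf", "azf",
                     "b1", "b2", "b3", "b4", "b5"))
})

test_that("a bent-finger offset survives the slow path and maps to bent", {
  # arm-dominant scratching curls all fingers; mid-bout bend states are 1
  a <- generate_action(action_spec("scratch_arm", duration_s = 10),
                       synth_config(seed = 17L))
  pc <- process_recording(a$recording)
  # the causal slow path holds a sustained curl for ~6 s; check 2-4 s
  mid <- 40:80
  expect_true(all(colMeans(pc$bend[mid, ]) > 0.9))
  expect_true(all(pc$bend %in% c(0L, 1L)))
})

test_that("scratch oscillations pass the fast path with a large band-power margin over idle", {
  cfg <- synth_config(seed = 18L)
  scratch <- generate_action(action_spec("scratch_finger"), cfg)
  idle <- generate_action(action_spec("idle"), cfg, seed = 19L)
  bp <- function(rec) {
    pc <- process_recording(rec)
    max(vapply(1:5, function(j) band_power(pc$filtered[, j], 20, 3, 8),
               numeric(1)))
  }
  expect_gt(bp(scratch$recording), 10 * bp(idle$recording))
})

test_that("short recordings are processed with a warm-up notice", {
  rec <- random_recording(n = 20)
  expect_message(process_recording(rec), "warm-up")
})
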