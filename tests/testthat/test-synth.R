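test_that("finger-dominant scratching oscillates in the scratch band on the index finger", {
  a <- generate_action(action_spec("scratch_finger"), synth_config(seed = 3L))
  # measured after the fast path, which removes the bend-offset step that
  # otherwise dominates the raw periodogram at low frequency
  pc <- process_recording(a$recording)
  f <- dominant_freq(pc$filtered[, 2], 20)
  expect_gte(f, 3)
  expect_lte(f, 8)
  expect_identical(unique(a$labels$labels), 1L)
})

test_that("arm-dominant scratching puts scratch-band energy on the accelerometer over bent fingers", {
  a <- generate_action(action_spec("scratch_arm"), synth_config(seed = 4L))
  f <- dominant_freq(a$recording$accel[, 2], 20)
  expect_gte(f, 3)
  expect_lte(f, 8)
  # sustained bend offset on every finger: mid-bout mean well above threshold
  mid <- 50:150
  expect_true(all(colMeans(a$recording$stretch[mid, ]) > 15))
})

test_that("idle with no noise and no drift is identically zero", {
  cfg <- synth_config(noise_sd_mohm = 0, noise_sd_g = 0, drift_amp_mohm = 0)
  a <- generate_action(action_spec("idle"), cfg)
  expect_true(all(raw_matrix(a$recording) == 0))
  expect_identical(unique(a$labels$labels), 0L)
})

test_that("rubbing with the x-axis option carries more AX scratch-band power than idle", {
  cfg <- synth_config(seed = 5L, rub_ax = TRUE)
  rub <- generate_action(action_spec("rub"), cfg)
  idle <- generate_action(action_spec("idle"), cfg, seed = 6L)
  bp_rub <- band_power(rub$recording$accel[, 1], 20, 3, 8)
  bp_idle <- band_power(idle$recording$accel[, 1], 20, 3, 8)
  expect_gt(bp_rub, bp_idle)
})

test_that("intensive bouts use the upper half of the frequency band", {
  cfg <- synth_config(seed = 8L)
  for (s in 1:5) {
    a <- generate_action(action_spec("scratch_finger", intensity = "intensive"),
                         cfg, seed = s)
    pc <- process_recording(a$recording)
    # upper half of [3, 8] Hz, with slack for frequency jitter and the
    # 0.1 Hz periodogram resolution
    expect_gte(dominant_freq(pc$filtered[, 2], 20), 5.3)
  }
})

test_that("identical seeds give bit-identical output", {
  cfg <- synth_config(seed = 42L)
  a1 <- generate_action(action_spec("scratch_arm"), cfg)
  a2 <- generate_action(action_spec("scratch_arm"), cfg)
  expect_identical(a1, a2)
  c1 <- generate_training_corpus(default_action_catalog(), 2, cfg)
  c2 <- generate_training_corpus(default_action_catalog(), 2, cfg)
  expect_identical(c1, c2)
})

test_that("the parameter error for a band outside Nyquist is raised", {
  expect_error(synth_config(scratch_freq_band_hz = c(3, 12)), "Nyquist")
})

test_that("a single-action script with no gap equals the action itself", {
  cfg <- synth_config(seed = 9L)
  spec <- action_spec("scratch_finger")
  ses <- generate_session(list(list(spec = spec, gap_s = 0)), cfg)
  solo <- generate_action(spec, cfg, seed = sigmaglove:::derive_seed(cfg$seed, 1L))
  expect_equal(ses$recording$stretch, solo$recording$stretch)
  expect_identical(ses$labels$labels, solo$labels$labels)
})

test_that("the 30-minute momentary-scratch preset has the documented shape", {
  cfg <- synth_config(seed = 10L)
  script <- session_preset_momentary()
  ses <- generate_session(script, cfg)
  expect_identical(n_samples(ses$recording), 36000L)
  ev <- labels_to_events(ses$labels, fs = 20)
  expect_identical(nrow(ev), 7L)
  expect_equal(ev[, "start_s"], seq(240, 1680, by = 240))
  # label bookkeeping: labels sum to the scripted scratch-bout samples
  expect_identical(sum(ses$labels$labels), 7L * 5L * 20L)
})

test_that("corpus size and class balance follow the catalog composition", {
  catalog <- default_action_catalog(duration_s = 2)
  corpus <- generate_training_corpus(catalog, 3, synth_config(seed = 2L))
  expect_length(corpus, length(catalog) * 3L)
  truth <- vapply(corpus, function(it) unique(it$labels$labels), integer(1))
  n_scratch_specs <- sum(vapply(catalog, `[[`, logical(1), "scratch_truth"))
  expect_identical(sum(truth), n_scratch_specs * 3L)
})

test_that("every scratch bout has a channel with more 3-8 Hz than 0-1 Hz power", {
  cfg <- synth_config(seed = 13L)
  specs <- unlist(lapply(c("scratch_finger", "scratch_arm", "rub"),
                         function(a) lapply(c("normal", "intensive"),
                                            function(i) action_spec(a, i))),
                  recursive = FALSE)
  for (s in seq_along(specs)) {
    a <- generate_action(specs[[s]], cfg, seed = 100L + s)
    raw <- raw_matrix(a$recording)
    ratio <- vapply(seq_len(8), function(j)
      band_power(raw[, j], 20, 3, 8) /
        max(band_power(raw[, j], 20, 0.01, 1), 1e-12), numeric(1))
    expect_gt(max(ratio), 1)
  }
})

test_that("idle segments never trip the bend threshold after processing", {
  cfg <- synth_config(seed = 21L)
  for (s in 1:5) {
    a <- generate_action(action_spec("idle", duration_s = 20), cfg, seed = s)
    pc <- process_recording(a$recording)
    expect_true(all(pc$bend == 0L))
  }
})
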