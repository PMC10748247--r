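test_that("confusion counts the four cells with scratch as the positive class", {
  cm <- confusion(c(1, 1, 0), c(1, 1, 0))
  expect_identical(unclass(cm)[c("tp", "fp", "tn", "fn")],
                   list(tp = 2L, fp = 0L, tn = 1L, fn = 0L))
  cm <- confusion(1, 0)
  expect_identical(cm$fp, 1L)
  expect_error(confusion(c(1, 0), 1), "lengths differ")
  withr::with_seed(11, {
    for (i in 1:10) {
      n <- sample(1:50, 1)
      p <- rbinom(n, 1, 0.5); t0 <- rbinom(n, 1, 0.5)
      cm <- confusion(p, t0)
      expect_identical(cm$tp + cm$fp + cm$tn + cm$fn, n)
    }
  })
})

test_that("metrics follow the standard ratio definitions", {
  cm <- confusion(c(rep(1, 5), rep(0, 5), rep(1, 10), rep(0, 80)),
                  c(rep(1, 10), rep(0, 90)))
  m <- classification_metrics(cm)
  expect_equal(m$sensitivity, 0.5)
  expect_equal(m$specificity, 80 / 90)
  expect_equal(m$precision, 5 / 15)
  expect_equal(m$npv, 80 / 85)
  expect_equal(m$accuracy, 85 / 100)
})

test_that("undefined ratios are NA, with the compatibility option printing precision 0", {
  # no true scratch windows: sensitivity undefined
  cm <- confusion(rep(0, 10), rep(0, 10))
  m <- classification_metrics(cm)
  expect_true(is.na(m$sensitivity))
  expect_true(is.na(m$precision))
  expect_equal(classification_metrics(cm, compat_precision = TRUE)$precision, 0)
  # perfect prediction: all defined metrics are 1
  cm <- confusion(c(1, 1, 0), c(1, 1, 0))
  m <- classification_metrics(cm)
  expect_true(all(unlist(m) == 1))
  # degenerate empty matrix
  m0 <- classification_metrics(confusion(integer(0), integer(0)))
  expect_true(all(is.na(unlist(m0))))
})

test_that("scratch time counts one stride per positive window", {
  st <- scratch_time(rep(1, 270), stride_s = 1, session_s = 1800)
  expect_identical(st$seconds, 270)
  st <- scratch_time(c(rep(1, 77), rep(0, 1723)), stride_s = 1,
                     session_s = 1800)
  expect_identical(st$seconds, 77)
  expect_equal(round_half_up(st$fraction, 2), 0.04)
  expect_identical(scratch_time(rep(0, 10), session_s = 100)$seconds, 0)
})

test_that("event detection requires one overlapping positive window per event", {
  # windows at 1 s stride; event fully covered by positives
  expect_equal(event_detection(rep(1, 10), seq(1, by = 20, length.out = 10),
                               cbind(2, 4)), 1.0)
  # no events at all -> NA
  expect_true(is.na(event_detection(rep(1, 10),
                                    seq(1, by = 20, length.out = 10),
                                    cbind(numeric(0), numeric(0)))))
  # three events, positives overlap only the first two
  starts <- seq(1, by = 20, length.out = 60)
  pred <- as.integer(starts < 20 * 30)
  events <- rbind(c(5, 8), c(20, 22), c(50, 55))
  expect_equal(event_detection(pred, starts, events), 2 / 3)
  expect_error(event_detection(1, 1, cbind(5, 4)), "end > start")
  expect_error(event_detection(1, 1, rbind(c(1, 5), c(4, 8))),
               "non-overlapping")
})

test_that("truth label runs convert to event intervals", {
  lab <- c(rep(0, 10), rep(1, 5), rep(0, 5), rep(1, 2))
  ev <- labels_to_events(lab, fs = 20)
  expect_equal(ev, cbind(start_s = c(0.5, 1.0), end_s = c(0.75, 1.1)))
})

test_that("cohort summaries exclude NA and use the sample standard deviation", {
  video <- c(77, 72, 92, 31, 20, 20)
  cs <- cohort_summary(list(video_s = video))
  expect_equal(round_half_up(cs$mean), 52)
  expect_equal(round_half_up(cs$sd), 32)
  sens <- c(0.21, 0.52, NA, 0.41, 0.47, NA)
  cs <- cohort_summary(list(sensitivity = sens))
  expect_identical(cs$n_used, 4L)
  expect_equal(round_half_up(cs$mean, 1), 0.4)
  expect_equal(round_half_up(cs$sd, 2), 0.14)
  # single defined value: mean is the value, SD undefined
  cs <- cohort_summary(list(x = c(3, NA)))
  expect_equal(cs$mean, 3)
  expect_true(is.na(cs$sd))
})

test_that("cohort summaries are permutation-invariant in subjects", {
  withr::with_seed(12, {
    v <- rnorm(8); v[c(2, 5)] <- NA
    perm <- sample(8)
    expect_equal(cohort_summary(list(m = v)), cohort_summary(list(m = v[perm])))
  })
})

test_that("the bundled pilot cohort table loads with its known shape", {
  pc <- pilot_cohort()
  expect_identical(nrow(pc), 6L)
  expect_identical(pc$subject, paste0("S", c(3:8)))
  expect_identical(sum(is.na(pc$sensitivity)), 2L)
})

test_that("subject reports assemble metrics, scratch times and event recall", {
  pred <- c(1, 1, 0, 0, 1)
  truth <- c(1, 0, 0, 1, 1)
  srep <- subject_report("S1", pred, truth, session_s = 100,
                         starts = seq(1, by = 20, length.out = 5),
                         truth_events = labels_to_events(
                           c(rep(1, 30), rep(0, 50), rep(1, 20)), fs = 20))
  expect_equal(srep$accuracy, 3 / 5)
  expect_equal(srep$scratch_time_pred_s, 3)
  expect_equal(srep$scratch_time_truth_s, 3)
  df <- as.data.frame(srep)
  expect_identical(nrow(df), 1L)
  expect_true(all(c("sensitivity", "npv", "event_tp_frac") %in% names(df)))
})
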