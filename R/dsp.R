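# Dual-path signal processing: 8 raw channels in, 13 processed channels out.
#
# Fast path: 4th-order 0.5 Hz high-pass Butterworth on all 8 channels,
# isolating the 3-8 Hz scratch oscillations from drift and posture shifts.
# Slow path (stretch only): 0.03 Hz high-pass to remove sensor drift, then a
# strided moving average (30-sample window, 20-sample step, held to full
# rate), then a 10 milliohm magnitude threshold giving a binary
# bent/extended state per finger. Filtering is causal (forward only) -- the
# device streams live, and zero-phase filtering would be unrealisable there.

PROCESSED_HEADER <- c("d1f", "d2f", "d3f", "d4f", "d5f", "axf", "ayf", "azf",
                      paste0("b", 1:5))

#' DSP configuration
#'
#' The slow-path cutoff defaults to 0.03 Hz: a 0.5 Hz high-pass would erase
#' the sustained bend offset that the 10 milliohm threshold needs to see,
#' while 0.03 Hz passes a multi-second finger curl nearly intact.
#'
#' @param fast_cutoff_hz fast-path high-pass cutoff (Hz).
#' @param slow_cutoff_hz slow-path high-pass cutoff (Hz).
#' @param order Butterworth order of the fast path.
#' @param slow_order Butterworth order of the slow path. Default 1: with
#'   causal filtering, a higher-order high-pass at 0.03 Hz forgets a
#'   sustained finger-curl offset within a few seconds and rings below
#'   zero, defeating the threshold; a first-order section keeps a 33
#'   milliohm curl above the 10 milliohm threshold for about 6 s.
#' @param ma_window,ma_step moving-average window and step, in samples.
#' @param bend_threshold_mohm magnitude threshold for the bent state;
#'   10 milliohm corresponds to about 3 mm of sensor extension.
#' @return A `dsp_config` object.
#' @export
dsp_config <- function(fast_cutoff_hz = 0.5, slow_cutoff_hz = 0.03,
                       order = 4, slow_order = 1, ma_window = 30,
                       ma_step = 20, bend_threshold_mohm = 10) {
  stopifnot(fast_cutoff_hz > 0, slow_cutoff_hz > 0, order >= 1,
            slow_order >= 1, ma_window >= 1, ma_step >= 1,
            bend_threshold_mohm > 0)
  structure(list(fast_cutoff_hz = fast_cutoff_hz,
                 slow_cutoff_hz = slow_cutoff_hz, order = order,
                 slow_order = slow_order,
                 ma_window = ma_window, ma_step = ma_step,
                 bend_threshold_mohm = bend_threshold_mohm),
            class = "dsp_config")
}

#' Causal high-pass Butterworth filter
#'
#' Forward (single-pass) filtering from zero initial state; the first few
#' seconds of output carry the start-up transient.
#'
#' @param x numeric series.
#' @param cutoff_hz -3 dB cutoff frequency in Hz; must lie below Nyquist.
#' @param order filter order.
#' @param fs sampling rate in Hz.
#' @return filtered series, same length as `x`.
#' @export
highpass_butterworth <- function(x, cutoff_hz, order = 4, fs = 20) {
  if (cutoff_hz <= 0 || cutoff_hz >= fs / 2)
    stop("cutoff_hz must lie in (0, fs/2)")
  if (order < 1) stop("order must be >= 1")
  if (length(x) == 0L) return(numeric(0))
  flt <- signal::butter(order, cutoff_hz / (fs / 2), type = "high")
  as.numeric(signal::filter(flt, x))
}

#' Strided moving average, held to full rate
#'
#' Window means are computed every `step` samples and expanded back to
#' per-sample length by zero-order hold, so the smoothed series stays
#' sample-aligned with the fast-path channels. A window shorter than
#' `window` at the tail averages the samples available; `window > length(x)`
#' degenerates to one global mean.
#'
#' @param x numeric series.
#' @param window window length in samples.
#' @param step stride between window starts in samples.
#' @return series of `length(x)`.
#' @export
moving_average <- function(x, window = 30, step = 20) {
  stopifnot(window >= 1, step >= 1)
  n <- length(x)
  if (n == 0L) return(numeric(0))
  if (window > n) return(rep(mean(x), n))
  starts <- seq(1L, n, by = step)
  means <- vapply(starts, function(s) mean(x[s:min(s + window - 1L, n)]),
                  numeric(1))
  out <- numeric(n)
  for (k in seq_along(starts)) {
    hi <- if (k < length(starts)) starts[k + 1L] - 1L else n
    out[starts[k]:hi] <- means[k]
  }
  out
}

#' Binary bend state from a slow-path stretch series
#'
#' A finger counts as bent where the processed signal magnitude reaches the
#' threshold (ties count as bent -- the scratch-sensitive choice).
#'
#' @param x_processed slow-path processed stretch series (milliohm).
#' @param threshold_mohm magnitude threshold.
#' @return integer series of 0 (extended) / 1 (bent).
#' @export
bend_state <- function(x_processed, threshold_mohm = 10) {
  stopifnot(threshold_mohm > 0)
  as.integer(abs(x_processed) >= threshold_mohm)
}

#' Construct a processed-channel container
#'
#' @param filtered N x 8 matrix of fast-path channels (d1f..d5f, axf..azf).
#' @param bend N x 5 binary matrix of per-finger bend states.
#' @param sample_rate_hz source sampling rate.
#' @return A `processed_channels` object (13 channels total).
#' @export
processed_channels <- function(filtered, bend, sample_rate_hz = 20) {
  filtered <- as.matrix(filtered)
  bend <- as.matrix(bend)
  if (ncol(filtered) != 8L) stop("filtered must have 8 channels")
  if (ncol(bend) != 5L) stop("bend must have 5 channels")
  if (nrow(filtered) != nrow(bend)) stop("channel lengths differ")
  if (nrow(bend) && !all(bend %in% c(0L, 1L)))
    stop("bend states must be strictly binary")
  colnames(filtered) <- PROCESSED_HEADER[1:8]
  colnames(bend) <- PROCESSED_HEADER[9:13]
  structure(list(filtered = filtered, bend = matrix(as.integer(bend),
                                                    nrow(bend), 5L,
                                                    dimnames = dimnames(bend)),
                 sample_rate_hz = sample_rate_hz),
            class = "processed_channels")
}

#' @export
print.processed_channels <- function(x, ...) {
  cat(sprintf("<processed_channels> %d samples @ %g Hz, 13 channels (8 filtered + 5 bend)\n",
              n_samples(x), x$sample_rate_hz))
  invisible(x)
}

#' All 13 processed channels as one matrix
#'
#' @param pc a `processed_channels`.
#' @return N x 13 matrix, fast-path channels first, bend states last.
#' @export
processed_matrix <- function(pc) {
  stopifnot(inherits(pc, "processed_channels"))
  cbind(pc$filtered, pc$bend)
}

#' Run both processing paths on a raw recording
#'
#' @param rec a [sensor_recording()].
#' @param cfg a [dsp_config()].
#' @return A [processed_channels()] with 13 channels.
#' @export
process_recording <- function(rec, cfg = dsp_config()) {
  stopifnot(inherits(rec, "sensor_recording"), inherits(cfg, "dsp_config"))
  fs <- rec$sample_rate_hz
  raw <- raw_matrix(rec)
  n <- nrow(raw)
  warmup <- 5 * fs
  if (n > 0L && n < warmup)
    message("recording shorter than the ~5 s filter warm-up; ",
            "processing anyway, expect start-up transients throughout")
  filtered <- apply(raw, 2L, highpass_butterworth,
                    cutoff_hz = cfg$fast_cutoff_hz, order = cfg$order, fs = fs)
  filtered <- matrix(filtered, nrow = n, ncol = 8L)
  bend <- matrix(0L, n, 5L)
  for (j in 1:5) {
    slow <- highpass_butterworth(rec$stretch[, j], cfg$slow_cutoff_hz,
                                 order = cfg$slow_order, fs = fs)
    slow <- moving_average(slow, window = cfg$ma_window, step = cfg$ma_step)
    bend[, j] <- bend_state(slow, cfg$bend_threshold_mohm)
  }
  processed_channels(filtered, bend, sample_rate_hz = fs)
}
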