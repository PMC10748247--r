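# Sliding-window segmentation.
#
# Processed channels are cut into 30-sample windows every 20 samples (1 s at
# 20 Hz). A window is anchored at its last sample -- "the point of sampling
# and the 29 samples before it" -- so windowing is causal. Incomplete
# windows are discarded. Each window gets one binary label: the median of
# its per-sample labels, with the exact 15/15 tie resolving to scratch.

#' Construct a window set
#'
#' @param windows W x window_len x 13 numeric array.
#' @param labels integer vector of W binary window labels.
#' @param starts integer vector of W start indices (1-based, into the source).
#' @param window_len,stride segmentation parameters in samples.
#' @param source_id optional per-window provenance tag (recycled).
#' @return A `window_set` object.
#' @export
window_set <- function(windows, labels, starts, window_len = 30, stride = 20,
                       source_id = NA_character_) {
  stopifnot(length(dim(windows)) == 3L)
  w <- dim(windows)[1L]
  if (dim(windows)[2L] != window_len)
    stop("windows must have exactly window_len samples each")
  if (length(labels) != w || length(starts) != w)
    stop("labels and starts must have one entry per window")
  labels <- as.integer(labels)
  if (w && !all(labels %in% c(0L, 1L))) stop("window labels must be binary")
  structure(list(windows = windows, labels = labels,
                 starts = as.integer(starts),
                 window_len = as.integer(window_len),
                 stride = as.integer(stride),
                 source_id = rep_len(as.character(source_id), w)),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d windows of %d samples (stride %d), %d scratch\n",
              n_windows(x), x$window_len, x$stride, sum(x$labels)))
  invisible(x)
}

#' Number of windows in a window set
#' @param x a `window_set`.
#' @return integer count.
#' @export
n_windows <- function(x) {
  stopifnot(inherits(x, "window_set"))
  dim(x$windows)[1L]
}

#' Extract the centered portion of a processed bout
#'
#' Training bouts run from rest to rest; the central slice drops the
#' transitions at both ends. When the trim is odd the extra sample is
#' dropped from the end.
#'
#' @param processed a [processed_channels()].
#' @param labels the aligned [label_track()].
#' @param duration_s length of the centered slice in seconds.
#' @return list with the sliced `processed` and `labels`.
#' @export
extract_center <- function(processed, labels, duration_s = 7) {
  stopifnot(inherits(processed, "processed_channels"),
            inherits(labels, "label_track"))
  n <- n_samples(processed)
  if (n != n_samples(labels)) stop("labels not aligned with processed data")
  len <- round(duration_s * processed$sample_rate_hz)
  if (len > n) stop("source shorter than the requested center slice")
  start <- (n - len) %/% 2L
  idx <- start + seq_len(len)
  list(processed = processed_channels(processed$filtered[idx, , drop = FALSE],
                                      processed$bend[idx, , drop = FALSE],
                                      processed$sample_rate_hz),
       labels = label_track(labels$labels[idx],
                            action_codes = labels$action_codes[idx],
                            source = labels$source))
}

#' Label one window from its per-sample labels
#'
#' The window label is the median of the per-sample binary labels; the
#' exact half-and-half tie resolves to 1 (scratch), favouring detection.
#'
#' @param point_labels binary vector, exactly one value per window sample.
#' @return 0 or 1.
#' @export
label_window <- function(point_labels) {
  if (!all(point_labels %in% c(0, 1))) stop("window labels must be binary")
  as.integer(mean(point_labels) >= 0.5)
}

#' Cut processed channels into labelled sliding windows
#'
#' Emits `floor((N - window_len) / stride) + 1` windows for
#' `N >= window_len`, none otherwise (incomplete windows are discarded).
#' Window k covers samples `1 + (k-1)*stride` through
#' `window_len + (k-1)*stride`.
#'
#' @param processed a [processed_channels()].
#' @param labels aligned [label_track()]; optional (`NULL` labels every
#'   window 0, for prediction-only use).
#' @param window_len,stride segmentation parameters in samples.
#' @param source_id provenance tag stored per window.
#' @return A [window_set()].
#' @export
make_windows <- function(processed, labels = NULL, window_len = 30,
                         stride = 20, source_id = NA_character_) {
  stopifnot(inherits(processed, "processed_channels"),
            window_len >= 1, stride >= 1)
  n <- n_samples(processed)
  mat <- processed_matrix(processed)
  w <- if (n >= window_len) (n - window_len) %/% stride + 1L else 0L
  arr <- array(0, dim = c(w, window_len, 13L))
  labs <- integer(w)
  starts <- integer(w)
  for (k in seq_len(w)) {
    s <- 1L + (k - 1L) * stride
    idx <- s:(s + window_len - 1L)
    arr[k, , ] <- mat[idx, ]
    starts[k] <- s
    if (!is.null(labels)) labs[k] <- label_window(labels$labels[idx])
  }
  window_set(arr, labs, starts, window_len = window_len, stride = stride,
             source_id = source_id)
}

#' Stack window sets from many actions into one
#'
#' Concatenates windows and labels; start indices stay expressed relative to
#' each window's own source, with `source_id` retaining provenance.
#'
#' @param sets list of [window_set()] with identical window geometry.
#' @return A single [window_set()].
#' @export
stack_windows <- function(sets) {
  sets <- Filter(function(s) n_windows(s) > 0L, sets)
  if (length(sets) == 0L)
    return(window_set(array(0, c(0L, 30L, 13L)), integer(0), integer(0)))
  wl <- unique(vapply(sets, function(s) s$window_len, integer(1)))
  st <- unique(vapply(sets, function(s) s$stride, integer(1)))
  if (length(wl) != 1L || length(st) != 1L)
    stop("window sets have incompatible geometry")
  total <- sum(vapply(sets, n_windows, integer(1)))
  arr <- array(0, dim = c(total, wl, 13L))
  at <- 0L
  for (s in sets) {
    w <- n_windows(s)
    arr[at + seq_len(w), , ] <- s$windows
    at <- at + w
  }
  window_set(arr,
             unlist(lapply(sets, `[[`, "labels")),
             unlist(lapply(sets, `[[`, "starts")),
             window_len = wl, stride = st,
             source_id = unlist(lapply(sets, `[[`, "source_id")))
}

#' Subset a window set
#'
#' @param set a [window_set()].
#' @param idx integer or logical index over windows.
#' @return A [window_set()] with the selected windows.
#' @export
subset_windows <- function(set, idx) {
  stopifnot(inherits(set, "window_set"))
  window_set(set$windows[idx, , , drop = FALSE], set$labels[idx],
             set$starts[idx], window_len = set$window_len,
             stride = set$stride, source_id = set$source_id[idx])
}

#' Full bout-to-windows pipeline for a labelled corpus
#'
#' Processes each bout, extracts the centered slice, windows it, and stacks
#' everything. Training bouts are uniformly labelled, so each window's
#' median label equals the bout truth.
#'
#' @param corpus list of `list(recording, labels)` from
#'   [generate_training_corpus()] (or equivalent real data).
#' @param dsp a [dsp_config()].
#' @param center_s centered-slice duration in seconds.
#' @param window_len,stride segmentation parameters.
#' @return A stacked [window_set()].
#' @export
corpus_windows <- function(corpus, dsp = dsp_config(), center_s = 7,
                           window_len = 30, stride = 20) {
  sets <- lapply(seq_along(corpus), function(i) {
    item <- corpus[[i]]
    pc <- process_recording(item$recording, dsp)
    sl <- extract_center(pc, item$labels, duration_s = center_s)
    make_windows(sl$processed, sl$labels, window_len = window_len,
                 stride = stride, source_id = as.character(i))
  })
  stack_windows(sets)
}
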