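#' @keywords internal
"_PACKAGE"

STRETCH_CHANNELS <- c("d1", "d2", "d3", "d4", "d5")
ACCEL_CHANNELS <- c("ax", "ay", "az")
RAW_CHANNELS <- c(STRETCH_CHANNELS, ACCEL_CHANNELS)

#' Construct a sensor recording
#'
#' A `sensor_recording` holds one session of raw glove data: five stretch
#' channels (resistance change in milliohm relative to the relaxed baseline,
#' finger order thumb `d1` to little `d5`) and three accelerometer axes in g
#' (`ax`, `ay`, `az`), all sampled at a common fixed rate.
#'
#' @param stretch numeric matrix, N samples x 5 columns (d1..d5), in milliohm.
#' @param accel numeric matrix, N samples x 3 columns (ax, ay, az), in g.
#' @param sample_rate_hz sampling rate in Hz; the glove streams at 20 Hz.
#' @param subject_id opaque subject identifier.
#' @param session_meta named list of free-form session annotations
#'   (e.g. clinical scores such as EASI or PP-NRS); carried, never computed on.
#' @return An object of class `sensor_recording`.
#' @export
sensor_recording <- function(stretch, accel, sample_rate_hz = 20,
                             subject_id = "anon", session_meta = list()) {
  stretch <- as.matrix(stretch)
  accel <- as.matrix(accel)
  if (nrow(stretch) == 0L) stretch <- matrix(numeric(0), 0L, 5L)
  if (nrow(accel) == 0L) accel <- matrix(numeric(0), 0L, 3L)
  if (ncol(stretch) != 5L) stop("stretch must have 5 channels (d1..d5)")
  if (ncol(accel) != 3L) stop("accel must have 3 channels (ax, ay, az)")
  if (nrow(stretch) != nrow(accel))
    stop("stretch and accel must have the same number of samples")
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1L ||
      sample_rate_hz <= 0)
    stop("sample_rate_hz must be a single positive number")
  colnames(stretch) <- STRETCH_CHANNELS
  colnames(accel) <- ACCEL_CHANNELS
  structure(
    list(stretch = stretch, accel = accel,
         sample_rate_hz = as.numeric(sample_rate_hz),
         subject_id = as.character(subject_id),
         session_meta = session_meta),
    class = "sensor_recording")
}

#' @export
print.sensor_recording <- function(x, ...) {
  cat(sprintf("<sensor_recording> subject=%s, %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, n_samples(x), x$sample_rate_hz,
              n_samples(x) / x$sample_rate_hz))
  invisible(x)
}

#' Number of samples in a recording-like object
#'
#' @param x a `sensor_recording`, `label_track` or `processed_channels`.
#' @return integer sample count.
#' @export
n_samples <- function(x) UseMethod("n_samples")

#' @export
n_samples.sensor_recording <- function(x) nrow(x$stretch)

#' @export
n_samples.label_track <- function(x) length(x$labels)

#' @export
n_samples.processed_channels <- function(x) nrow(x$filtered)

#' All eight raw channels as a single matrix
#'
#' @param rec a `sensor_recording`.
#' @return N x 8 numeric matrix, columns d1..d5, ax, ay, az.
#' @export
raw_matrix <- function(rec) {
  stopifnot(inherits(rec, "sensor_recording"))
  cbind(rec$stretch, rec$accel)
}

#' Construct a per-sample label track
#'
#' Binary scratch labels aligned one-to-one with the samples of a recording:
#' 1 = scratching (including rubbing, which is grouped with scratching),
#' 0 = anything else.
#'
#' @param labels integer vector of 0/1, one per sample.
#' @param action_codes optional character vector of per-sample action names.
#' @param source provenance of the labels: `"manual"` (human annotation),
#'   `"model"` (classifier output) or `"synthetic_truth"` (generator truth).
#' @return An object of class `label_track`.
#' @export
label_track <- function(labels, action_codes = NULL,
                        source = c("synthetic_truth", "manual", "model")) {
  source <- match.arg(source)
  labels <- as.integer(labels)
  if (length(labels) && !all(labels %in% c(0L, 1L)))
    stop("labels must be strictly binary (0 or 1)")
  if (!is.null(action_codes) && length(action_codes) != length(labels))
    stop("action_codes must align with labels")
  structure(list(labels = labels, action_codes = action_codes,
                 source = source),
            class = "label_track")
}

#' @export
print.label_track <- function(x, ...) {
  cat(sprintf("<label_track> %d samples, %d positive (%s)\n",
              length(x$labels), sum(x$labels), x$source))
  invisible(x)
}

#' Concatenate recordings and label tracks in time
#'
#' @param recs list of `sensor_recording` with identical sample rates.
#' @param tracks list of `label_track`, aligned with `recs`.
#' @return list with elements `recording` and `labels`.
#' @export
concat_recordings <- function(recs, tracks) {
  stopifnot(length(recs) == length(tracks), length(recs) >= 1L)
  fs <- unique(vapply(recs, function(r) r$sample_rate_hz, numeric(1)))
  if (length(fs) != 1L) stop("all recordings must share a sample rate")
  rec <- sensor_recording(
    stretch = do.call(rbind, lapply(recs, function(r) r$stretch)),
    accel = do.call(rbind, lapply(recs, function(r) r$accel)),
    sample_rate_hz = fs,
    subject_id = recs[[1L]]$subject_id,
    session_meta = recs[[1L]]$session_meta)
  codes <- lapply(tracks, function(t) {
    if (is.null(t$action_codes)) rep(NA_character_, length(t$labels))
    else t$action_codes
  })
  lab <- label_track(unlist(lapply(tracks, function(t) t$labels)),
                     action_codes = unlist(codes),
                     source = tracks[[1L]]$source)
  list(recording = rec, labels = lab)
}

# run fn() under a fixed RNG seed, restoring the caller's RNG state after
with_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  fn()
}

# deterministic per-item seed derived from a base seed; stays below 2^31
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + as.double(i) * 16807) %% 2147483647)
}
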