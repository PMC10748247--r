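# On-disk formats.
#
# The device's own companion application format is undocumented, so the
# package defines a plain-text exchange dialect: comma-separated, one header
# row, UTF-8, '.' decimal separator. Raw recordings carry an explicit time
# column, but sample_rate_hz is authoritative; a disagreement larger than one
# sample over the file is a warning (hardware clocks jitter), never an error.

RECORDING_HEADER <- c("t_s", "d1_mohm", "d2_mohm", "d3_mohm", "d4_mohm",
                      "d5_mohm", "ax_g", "ay_g", "az_g")

#' Read a raw glove recording from CSV
#'
#' Expects exactly the columns `t_s, d1_mohm..d5_mohm, ax_g, ay_g, az_g` in
#' that order. Malformed numeric cells are an error, never silently dropped;
#' extra or missing columns are a schema error; non-monotone timestamps are a
#' format error. An empty body yields a zero-sample recording.
#'
#' @param path path to a recording CSV written by [write_recording()].
#' @param sample_rate_hz authoritative sampling rate in Hz.
#' @param subject_id subject identifier to attach.
#' @return A [sensor_recording()].
#' @export
read_recording <- function(path, sample_rate_hz = 20, subject_id = "anon") {
  if (!file.exists(path)) stop("file not found: ", path)
  head_line <- readLines(path, n = 1L)
  cols <- strsplit(head_line, ",", fixed = TRUE)[[1L]]
  if (!identical(trimws(cols), RECORDING_HEADER))
    stop("schema error: expected columns ", paste(RECORDING_HEADER, collapse = ","),
         " but found ", paste(cols, collapse = ","))
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, fileEncoding = "UTF-8")
  if (nrow(df) == 0L) {
    return(sensor_recording(matrix(numeric(0), 0, 5), matrix(numeric(0), 0, 3),
                            sample_rate_hz = sample_rate_hz,
                            subject_id = subject_id))
  }
  num <- vapply(df, function(col) {
    v <- suppressWarnings(as.numeric(col))
    if (anyNA(v)) stop("malformed numeric cell in recording file")
    v
  }, numeric(nrow(df)))
  num <- matrix(num, nrow = nrow(df),
                dimnames = list(NULL, RECORDING_HEADER))
  t_s <- num[, "t_s"]
  if (is.unsorted(t_s, strictly = TRUE))
    stop("format error: timestamps must be strictly increasing")
  expected_span <- (nrow(num) - 1L) / sample_rate_hz
  if (abs((t_s[length(t_s)] - t_s[1L]) - expected_span) > 1 / sample_rate_hz)
    warning("timestamp span disagrees with sample_rate_hz by more than one sample; ",
            "sample_rate_hz is authoritative")
  sensor_recording(stretch = num[, 2:6, drop = FALSE],
                   accel = num[, 7:9, drop = FALSE],
                   sample_rate_hz = sample_rate_hz,
                   subject_id = subject_id)
}

#' Write a raw glove recording to CSV
#'
#' Emits the schema read by [read_recording()]; timestamps are regenerated
#' from the sample rate. Non-finite channel values are refused.
#'
#' @param rec a [sensor_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "sensor_recording"))
  mat <- raw_matrix(rec)
  if (nrow(mat) && !all(is.finite(mat)))
    stop("recording contains non-finite values; refusing to write")
  n <- nrow(mat)
  t_s <- if (n) (seq_len(n) - 1L) / rec$sample_rate_hz else numeric(0)
  df <- data.frame(t_s, mat)
  names(df) <- RECORDING_HEADER
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a per-sample label track
#'
#' Label files hold one 0/1 value per line under a `label` header, optionally
#' with an `action` column carrying per-sample action codes.
#'
#' @param path label CSV path.
#' @param source provenance tag to attach, see [label_track()].
#' @return A [label_track()].
#' @export
read_labels <- function(path, source = "manual") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  if (!"label" %in% names(df)) stop("schema error: missing 'label' column")
  lab <- df$label
  if (length(lab) && !all(lab %in% c(0, 1)))
    stop("labels must be strictly binary (0 or 1)")
  codes <- if ("action" %in% names(df)) as.character(df$action) else NULL
  label_track(lab, action_codes = codes, source = source)
}

#' @rdname read_labels
#' @param track a [label_track()].
#' @export
write_labels <- function(track, path) {
  stopifnot(inherits(track, "label_track"))
  df <- data.frame(label = track$labels)
  if (!is.null(track$action_codes)) df$action <- track$action_codes
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write / read the 13-channel processed matrix
#'
#' Columns `d1f..d5f, axf, ayf, azf` (fast-path filtered) then `b1..b5`
#' (binary bend states).
#'
#' @param pc a `processed_channels` object from [process_recording()].
#' @param path CSV path.
#' @return `path` (write) or a `processed_channels` (read).
#' @export
write_processed <- function(pc, path) {
  stopifnot(inherits(pc, "processed_channels"))
  df <- data.frame(pc$filtered, pc$bend)
  names(df) <- PROCESSED_HEADER
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_processed
#' @param sample_rate_hz sampling rate of the source recording.
#' @export
read_processed <- function(path, sample_rate_hz = 20) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  if (!identical(names(df), PROCESSED_HEADER))
    stop("schema error: expected columns ", paste(PROCESSED_HEADER, collapse = ","))
  processed_channels(filtered = as.matrix(df[, 1:8]),
                     bend = as.matrix(df[, 9:13]),
                     sample_rate_hz = sample_rate_hz)
}
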