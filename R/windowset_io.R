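# Portable single-file window-set container (JSON): window array with its
# dimensions, labels, starts, geometry and provenance. Plain text, so it
# crosses platforms and languages without an R-specific serialisation.

#' Write / read a window set as a portable JSON bundle
#'
#' @param set a [window_set()].
#' @param path `.json` output path.
#' @return `path` (write) or the restored [window_set()] (read).
#' @export
write_windows <- function(set, path) {
  stopifnot(inherits(set, "window_set"))
  payload <- list(dim = dim(set$windows),
                  windows = as.numeric(set$windows),
                  labels = set$labels,
                  starts = set$starts,
                  window_len = set$window_len,
                  stride = set$stride,
                  source_id = set$source_id)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_windows
#' @export
read_windows <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  window_set(array(p$windows, dim = p$dim),
             labels = p$labels, starts = p$starts,
             window_len = p$window_len, stride = p$stride,
             source_id = if (length(p$source_id)) p$source_id
                         else NA_character_)
}
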