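# Window- and event-level evaluation.
#
# Window predictions are compared against truth labels in a standard
# confusion matrix (class 1 = scratch). Ratios with empty denominators are
# NA, never 0/0 artifacts: a subject who never scratched with the
# instrumented hand has undefined sensitivity. Scratch time counts one
# stride (1 s at the default geometry) per positive window. Event-level
# recall asks, for each ground-truth scratch event, whether at least one
# positive window overlaps it in time. Cohort summaries are NA-excluding
# means with sample (n-1) standard deviations.

#' Confusion matrix of window labels
#'
#' @param pred,truth equal-length binary vectors (1 = scratch).
#' @return A `confusion_matrix` with counts `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("pred and truth lengths differ")
  if (!all(pred %in% c(0, 1)) || !all(truth %in% c(0, 1)))
    stop("labels must be binary")
  structure(list(tp = sum(pred == 1 & truth == 1),
                 fp = sum(pred == 1 & truth == 0),
                 tn = sum(pred == 0 & truth == 0),
                 fn = sum(pred == 0 & truth == 1)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion> tp=%d fp=%d tn=%d fn=%d\n", x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Classification metrics from a confusion matrix
#'
#' @param cm a [confusion()] result.
#' @param compat_precision if TRUE (Table-compatibility mode), an undefined
#'   precision (no positive predictions) is reported as 0 rather than NA.
#' @return named list: sensitivity, specificity, precision, npv, accuracy.
#'   Undefined ratios are NA (see `compat_precision`).
#' @export
classification_metrics <- function(cm, compat_precision = FALSE) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$tp + cm$fp + cm$tn + cm$fn
  precision <- safe_ratio(cm$tp, cm$tp + cm$fp)
  if (compat_precision && is.na(precision)) precision <- 0
  list(sensitivity = safe_ratio(cm$tp, cm$tp + cm$fn),
       specificity = safe_ratio(cm$tn, cm$tn + cm$fp),
       precision = precision,
       npv = safe_ratio(cm$tn, cm$tn + cm$fn),
       accuracy = safe_ratio(cm$tp + cm$tn, total))
}

#' Total scratch time from window labels
#'
#' Each positive window contributes one stride of wall time (1 s at the
#' 30-sample/20-stride, 20 Hz geometry) -- the only mapping that yields
#' integer second totals for 1 s strides.
#'
#' @param window_labels binary window labels.
#' @param stride_s window stride in seconds.
#' @param session_s total session duration in seconds.
#' @return list with `seconds` and `fraction` (of session, unrounded; round
#'   to 2 decimals for display).
#' @export
scratch_time <- function(window_labels, stride_s = 1, session_s) {
  stopifnot(session_s > 0, all(window_labels %in% c(0, 1)))
  seconds <- sum(window_labels == 1) * stride_s
  list(seconds = seconds, fraction = seconds / session_s)
}

#' Event-level detection fraction
#'
#' An event is detected when at least one positive window overlaps it in
#' time; a window anchored at sample s covers
#' `[(s-1)/fs, (s-1+window_len)/fs)` seconds.
#'
#' @param pred_labels binary window labels.
#' @param starts 1-based window start samples, aligned with `pred_labels`.
#' @param truth_events two-column matrix or data frame of event
#'   `[start_s, end_s]` intervals, non-overlapping and in order.
#' @param fs sampling rate in Hz.
#' @param window_len window length in samples.
#' @return fraction of events detected, or NA when there are no events.
#' @export
event_detection <- function(pred_labels, starts, truth_events, fs = 20,
                            window_len = 30) {
  ev <- as.matrix(truth_events)
  if (length(ev) == 0L || nrow(ev) == 0L) return(NA_real_)
  if (ncol(ev) != 2L || any(ev[, 2L] <= ev[, 1L]))
    stop("truth_events must be [start_s, end_s] rows with end > start")
  if (nrow(ev) > 1L && any(ev[-1L, 1L] < ev[-nrow(ev), 2L]))
    stop("truth_events must be non-overlapping and ordered")
  pos <- which(pred_labels == 1)
  if (length(pos) == 0L) return(0)
  w_lo <- (starts[pos] - 1) / fs
  w_hi <- (starts[pos] - 1 + window_len) / fs
  detected <- vapply(seq_len(nrow(ev)), function(i)
    any(w_lo < ev[i, 2L] & w_hi > ev[i, 1L]), logical(1))
  mean(detected)
}

#' Turn per-sample truth labels into scratch events
#'
#' @param labels a [label_track()] or binary vector.
#' @param fs sampling rate in Hz.
#' @return matrix of `[start_s, end_s)` rows, one per contiguous run of 1s.
#' @export
labels_to_events <- function(labels, fs = 20) {
  v <- if (inherits(labels, "label_track")) labels$labels else labels
  r <- rle(as.integer(v))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values == 1L
  cbind(start_s = (starts[keep] - 1L) / fs, end_s = ends[keep] / fs)
}

#' Per-subject evaluation report
#'
#' @param subject_id subject identifier.
#' @param pred,truth binary window labels.
#' @param starts window start samples (for event-level recall); optional.
#' @param truth_events event intervals (see [event_detection()]); optional.
#' @param session_s session duration in seconds.
#' @param stride_s window stride in seconds.
#' @param fs,window_len window geometry for event overlap.
#' @param meta named list of carried metadata (e.g. EASI, PP-NRS).
#' @param compat_precision see [classification_metrics()].
#' @return A `subject_report` (also a one-row data frame via
#'   [as.data.frame()]).
#' @export
subject_report <- function(subject_id, pred, truth, session_s,
                           starts = NULL, truth_events = NULL,
                           stride_s = 1, fs = 20, window_len = 30,
                           meta = list(), compat_precision = FALSE) {
  cm <- confusion(pred, truth)
  m <- classification_metrics(cm, compat_precision = compat_precision)
  st_t <- scratch_time(truth, stride_s, session_s)
  st_p <- scratch_time(pred, stride_s, session_s)
  ev <- if (!is.null(truth_events) && !is.null(starts))
    event_detection(pred, starts, truth_events, fs = fs,
                    window_len = window_len)
  else NA_real_
  structure(c(list(subject_id = subject_id, confusion = cm),
              m,
              list(scratch_time_truth_s = st_t$seconds,
                   scratch_frac_truth = st_t$fraction,
                   scratch_time_pred_s = st_p$seconds,
                   scratch_frac_pred = st_p$fraction,
                   event_tp_frac = ev,
                   meta = meta)),
            class = "subject_report")
}

#' @export
print.subject_report <- function(x, ...) {
  cat(sprintf("<subject_report> %s: acc=%.2f sens=%s spec=%.2f scratch %ds pred / %ds truth\n",
              x$subject_id, x$accuracy,
              if (is.na(x$sensitivity)) "NA" else sprintf("%.2f", x$sensitivity),
              x$specificity, x$scratch_time_pred_s, x$scratch_time_truth_s))
  invisible(x)
}

#' @export
as.data.frame.subject_report <- function(x, ...) {
  data.frame(subject_id = x$subject_id,
             tp = x$confusion$tp, fp = x$confusion$fp,
             tn = x$confusion$tn, fn = x$confusion$fn,
             sensitivity = x$sensitivity, specificity = x$specificity,
             precision = x$precision, npv = x$npv, accuracy = x$accuracy,
             scratch_time_truth_s = x$scratch_time_truth_s,
             scratch_frac_truth = x$scratch_frac_truth,
             scratch_time_pred_s = x$scratch_time_pred_s,
             scratch_frac_pred = x$scratch_frac_pred,
             event_tp_frac = x$event_tp_frac)
}

#' NA-aware cohort summary of per-subject metrics
#'
#' For each metric column: mean and sample (n-1) standard deviation over the
#' subjects with a defined value; NA values are excluded, never imputed.
#' A single defined value has a mean but an NA standard deviation.
#'
#' @param values_by_metric a data frame or named list whose entries are
#'   numeric per-subject vectors (NAs allowed).
#' @return data frame with columns `metric`, `mean`, `sd`, `n_used`.
#' @export
cohort_summary <- function(values_by_metric) {
  values_by_metric <- as.list(values_by_metric)
  stopifnot(length(values_by_metric) >= 1L)
  rows <- lapply(names(values_by_metric), function(nm) {
    v <- values_by_metric[[nm]]
    v <- v[!is.na(v)]
    data.frame(metric = nm,
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) >= 2L) stats::sd(v) else NA_real_,
               n_used = length(v))
  })
  do.call(rbind, rows)
}

#' Published pilot-cohort reference table
#'
#' Per-subject pilot-study values bundled with the package: clinical scores,
#' video- and glove-derived scratch times, confusion-derived metrics and
#' event-level detection for the six analysed subjects. Two subjects (S5,
#' S8) scratched only with the uninstrumented hand, so their sensitivity is
#' undefined (NA) and their precision prints as 0 in the source table.
#' Used to verify the package's NA-aware summary arithmetic against the
#' published Mean column.
#'
#' @return data frame, one row per subject.
#' @export
pilot_cohort <- function() {
  path <- system.file("extdata", "pilot_cohort.csv", package = "sigmaglove",
                      mustWork = TRUE)
  utils::read.csv(path)
}

#' Summarise a cohort table the way the published table does
#'
#' Runs [cohort_summary()] over every numeric metric column of a
#' per-subject table such as [pilot_cohort()].
#'
#' @param cohort data frame with a `subject` column and numeric metric
#'   columns.
#' @return data frame from [cohort_summary()].
#' @export
summarise_cohort_table <- function(cohort) {
  num <- cohort[, setdiff(names(cohort), "subject"), drop = FALSE]
  num <- num[, vapply(num, is.numeric, logical(1)), drop = FALSE]
  cohort_summary(num)
}

#' Round half away from zero at a fixed number of decimals
#'
#' Display rounding used for table output (R's `round` rounds half to even).
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
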