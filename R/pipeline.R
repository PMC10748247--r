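# End-to-end orchestration: simulate -> process -> window -> train ->
# predict -> evaluate -> report. Each stage reads the previous stage's
# documented files from the output directory and writes its own; a manifest
# records the seed, the stages run, and MD5 hashes of every artifact, so a
# rerun with the same seed is verifiably identical. No stage mutates an
# upstream artifact.

PIPELINE_STAGES <- c("simulate", "process", "window", "train", "predict",
                     "evaluate", "report")

#' Pipeline run configuration
#'
#' Bundles the per-module configurations with a global seed and output
#' directory. Any field left NULL takes the module default; the global seed
#' overrides the seeds inside `synth` and `model`.
#'
#' @param out_dir output directory for all artifacts.
#' @param seed global integer seed.
#' @param synth a [synth_config()].
#' @param dsp a [dsp_config()].
#' @param model a [model_config()].
#' @param catalog training-action catalog, see [default_action_catalog()].
#' @param n_reps repetitions per catalog action for the training corpus.
#' @param center_s,window_len,stride windowing parameters.
#' @param session_script validation-session script,
#'   see [session_preset_momentary()].
#' @return A `run_config` object.
#' @export
run_config <- function(out_dir = tempfile("sigmaglove_run_"), seed = 1L,
                       synth = NULL, dsp = NULL, model = NULL,
                       catalog = NULL, n_reps = 10L,
                       center_s = 7, window_len = 30L, stride = 20L,
                       session_script = NULL) {
  seed <- as.integer(seed)
  synth <- synth %||% synth_config(seed = seed)
  synth$seed <- seed
  model <- model %||% model_config(seed = seed)
  model$seed <- seed
  structure(list(out_dir = out_dir, seed = seed, synth = synth,
                 dsp = dsp %||% dsp_config(), model = model,
                 catalog = catalog %||% default_action_catalog(),
                 n_reps = as.integer(n_reps), center_s = center_s,
                 window_len = as.integer(window_len),
                 stride = as.integer(stride),
                 session_script = session_script %||%
                   session_preset_momentary()),
            class = "run_config")
}

pipeline_paths <- function(out_dir) {
  list(corpus_dir = file.path(out_dir, "corpus"),
       session_rec = file.path(out_dir, "session_recording.csv"),
       session_lab = file.path(out_dir, "session_labels.csv"),
       processed = file.path(out_dir, "session_processed.csv"),
       windows = file.path(out_dir, "session_windows.json"),
       model = file.path(out_dir, "model.json"),
       pred = file.path(out_dir, "pred_labels.csv"),
       report = file.path(out_dir, "subject_report.csv"),
       summary = file.path(out_dir, "cohort_summary.csv"),
       manifest = file.path(out_dir, "manifest.json"))
}

need_artifact <- function(path, produced_by) {
  if (!file.exists(path))
    stop("missing artifact ", path, "; run the '", produced_by,
         "' stage first", call. = FALSE)
  path
}

#' Run the scratch-detection pipeline
#'
#' @param cfg a [run_config()].
#' @param stages subset of
#'   `c("simulate","process","window","train","predict","evaluate","report")`;
#'   stages always execute in pipeline order.
#' @return named list of artifact paths, invisibly.
#' @export
run_pipeline <- function(cfg, stages = PIPELINE_STAGES) {
  stopifnot(inherits(cfg, "run_config"))
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  p <- pipeline_paths(cfg$out_dir)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  if ("simulate" %in% stages) {
    dir.create(p$corpus_dir, showWarnings = FALSE)
    corpus <- generate_training_corpus(cfg$catalog, cfg$n_reps, cfg$synth)
    for (i in seq_along(corpus)) {
      write_recording(corpus[[i]]$recording,
                      file.path(p$corpus_dir, sprintf("rec_%03d.csv", i)))
      write_labels(corpus[[i]]$labels,
                   file.path(p$corpus_dir, sprintf("lab_%03d.csv", i)))
    }
    ses_cfg <- cfg$synth
    ses_cfg$seed <- derive_seed(cfg$seed, 999L)
    ses <- generate_session(cfg$session_script, ses_cfg)
    write_recording(ses$recording, p$session_rec)
    write_labels(ses$labels, p$session_lab)
  }

  if ("process" %in% stages) {
    rec <- read_recording(need_artifact(p$session_rec, "simulate"),
                          sample_rate_hz = cfg$synth$sample_rate_hz)
    write_processed(process_recording(rec, cfg$dsp), p$processed)
  }

  if ("window" %in% stages) {
    pc <- read_processed(need_artifact(p$processed, "process"),
                         sample_rate_hz = cfg$synth$sample_rate_hz)
    lab <- read_labels(need_artifact(p$session_lab, "simulate"),
                       source = "synthetic_truth")
    write_windows(make_windows(pc, lab, window_len = cfg$window_len,
                               stride = cfg$stride, source_id = "session"),
                  p$windows)
  }

  if ("train" %in% stages) {
    need_artifact(file.path(p$corpus_dir, "rec_001.csv"), "simulate")
    n_items <- length(list.files(p$corpus_dir, pattern = "^rec_"))
    corpus <- lapply(seq_len(n_items), function(i) list(
      recording = read_recording(
        file.path(p$corpus_dir, sprintf("rec_%03d.csv", i)),
        sample_rate_hz = cfg$synth$sample_rate_hz),
      labels = read_labels(
        file.path(p$corpus_dir, sprintf("lab_%03d.csv", i)),
        source = "synthetic_truth")))
    train_set <- corpus_windows(corpus, cfg$dsp, center_s = cfg$center_s,
                                window_len = cfg$window_len,
                                stride = cfg$stride)
    fitted <- train_model(build_model(cfg$model), train_set)
    save_model(fitted, p$model)
  }

  if ("predict" %in% stages) {
    fitted <- load_model(need_artifact(p$model, "train"))
    set <- read_windows(need_artifact(p$windows, "window"))
    pred <- stats::predict(fitted, set)
    utils::write.csv(data.frame(start = set$starts, label = pred),
                     p$pred, row.names = FALSE, quote = FALSE)
  }

  if ("evaluate" %in% stages) {
    pred_df <- utils::read.csv(need_artifact(p$pred, "predict"))
    set <- read_windows(need_artifact(p$windows, "window"))
    lab <- read_labels(need_artifact(p$session_lab, "simulate"),
                       source = "synthetic_truth")
    fs <- cfg$synth$sample_rate_hz
    srep <- subject_report(
      "synthetic", pred = pred_df$label, truth = set$labels,
      session_s = length(lab$labels) / fs,
      starts = set$starts, truth_events = labels_to_events(lab, fs = fs),
      stride_s = cfg$stride / fs, fs = fs, window_len = cfg$window_len)
    utils::write.csv(as.data.frame(srep), p$report, row.names = FALSE)
  }

  if ("report" %in% stages) {
    rep_df <- utils::read.csv(need_artifact(p$report, "evaluate"))
    metrics <- rep_df[, c("sensitivity", "specificity", "precision", "npv",
                          "accuracy", "scratch_time_pred_s",
                          "event_tp_frac"), drop = FALSE]
    utils::write.csv(cohort_summary(metrics), p$summary, row.names = FALSE)
  }

  arts <- Filter(file.exists,
                 unlist(p[setdiff(names(p), c("manifest", "corpus_dir"))]))
  if (dir.exists(p$corpus_dir))
    arts <- c(arts, list.files(p$corpus_dir, full.names = TRUE))
  manifest <- list(package_version =
                     as.character(utils::packageVersion("sigmaglove")),
                   seed = cfg$seed, stages = stages,
                   created = format(Sys.time(), tz = "UTC"),
                   hashes = as.list(tools::md5sum(arts)))
  jsonlite::write_json(manifest, p$manifest, auto_unbox = TRUE, digits = NA)
  invisible(p)
}
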