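# sigmaglove

Scratch detection from sensorised-glove recordings for atopic dermatitis
research.

Scratching frequency and duration are an objective proxy for itch, the
symptom that drives treatment decisions in atopic dermatitis — but the
standard severity instruments (EASI, PP-NRS, SCORAD) are subjective, and
video annotation is intrusive and slow. A glove instrumented with five
microtubular stretch sensors (one per finger, resistance change in mΩ) and
a palm-mounted 3-axis accelerometer, sampled at 20 Hz, can flag scratching
automatically: finger-dominant scratching appears as 3–8 Hz oscillations on
the stretch channels over a bent-finger baseline offset, arm-dominant
scratching as the same band on the accelerometer with all fingers curled.

This package implements that detection pipeline end to end, with a
synthetic-signal generator standing in for the (non-public) glove
recordings:

* **`synth`** — labelled synthetic recordings: scratch/rub bouts with the
  two spectral signatures, everyday confounder actions, drift and noise;
  scripted sessions; seeded corpora.
* **`dsp`** — dual-path processing, 8 raw → 13 processed channels:
  a 4th-order 0.5 Hz high-pass Butterworth on all channels (fast path) and
  a 0.03 Hz high-pass → 30/20 moving average → 10 mΩ threshold giving
  binary per-finger bend states (slow path).
* **`windowing`** — central 7 s of each bout, causal 30-sample windows at a
  20-sample (1 s) stride, median window labels with ties to scratch.
* **`model`** — the CNN-LSTM window classifier
  (conv 32 → conv 64 → max-pool → LSTM 16 → dense 64 → softmax),
  implemented natively in vectorised R with Adam and full
  backpropagation through time, plus a deterministic spectral rule
  baseline; JSON model persistence.
* **`evaluation`** — confusion-matrix metrics with NA-aware semantics
  (undefined ratios are NA, excluded from cohort means, never imputed),
  scratch-time totals, event-level recall, and mean ± SD cohort summaries;
  the published pilot-cohort table ships as reference data.
* **`pipeline`** — `run_pipeline()` wires
  simulate → process → window → train → predict → evaluate → report with a
  hash manifest; `inst/cli/sigma.R` exposes the stages as subcommands.

## Worked example

Train on a synthetic corpus and score a scripted 30-minute session in
which the wearer scratches for 5 s every 4 minutes:

```r
library(sigmaglove)

# 1. simulate a labelled training corpus and a 30-minute validation session
cfg <- synth_config(seed = 42)
corpus <- generate_training_corpus(default_action_catalog(), n_reps = 10, cfg)
session <- generate_session(session_preset_momentary(), cfg)

# 2. process, window, train
train_set <- corpus_windows(corpus)
model <- train_model(build_model(model_config(seed = 42)), train_set)

# 3. score the session
proc <- process_recording(session$recording)
windows <- make_windows(proc, session$labels)
pred <- predict(model, windows)

# 4. evaluate
subject_report("demo", pred = pred, truth = windows$labels,
               session_s = n_samples(session$recording) / 20,
               starts = windows$starts,
               truth_events = labels_to_events(session$labels))
#> <subject_report> demo: acc=1.00 sens=1.00 spec=1.00 scratch 36s pred / 35s truth
```

All 7 scratch bouts are recovered (window accuracy, sensitivity and
specificity 1.00 on this clean session); the predicted scratch time is
36 s against 35 s of scripted truth — one extra boundary window, labelled
scratch by the tie-favouring median rule. On held-out synthetic bouts the
classifier typically scores ≳0.95 window accuracy; expectations on real
daytime recordings are far lower (abundant unmodelled hand actions), which
is precisely what the pilot-cohort reference table documents.

The NA-aware cohort arithmetic:

```r
cs <- summarise_cohort_table(pilot_cohort())
subset(cs, metric == "sensitivity")
#>        metric   mean        sd n_used
#> 7 sensitivity 0.4025 0.1364857      4
```

Two of six subjects scratched only with the uninstrumented hand; their
undefined sensitivity is excluded (n_used = 4), reproducing the published
0.4 ± 0.14.

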