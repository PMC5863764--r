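# Shared settings for the analysis workflow. Sourced by every numbered
# driver. Cohort scale is kept modest so the full workflow runs in a few
# minutes on one CPU; the package's tests exercise the same code at both
# smaller and larger scales.

library(naptools)

N_SUBJECTS <- 8
COHORT_CFG <- sim_config(
  n_subjects = N_SUBJECTS,
  duration = 600,            # 10 min of mostly N2/N3 per subject
  behavior_effect = 0.2,
  seed = 2024
)

FIXTURE_DIR <- "results/fixtures"
TABLE_DIR <- "results/tables"
dir.create(FIXTURE_DIR, recursive = TRUE, showWarnings = FALSE)
dir.create(TABLE_DIR, recursive = TRUE, showWarnings = FALSE)

subject_paths <- function(s) {
  stem <- sprintf("subject%02d", s)
  c(edf = file.path(FIXTURE_DIR, paste0(stem, ".edf")),
    events = file.path(FIXTURE_DIR, paste0(stem, "_events.tsv")),
    hypnogram = file.path(FIXTURE_DIR, paste0(stem, "_hypnogram.tsv")),
    truth = file.path(FIXTURE_DIR, paste0(stem, "_truth.json")))
}

load_subject <- function(s) {
  p <- subject_paths(s)
  rec <- read_recording(p["edf"], p["events"], p["hypnogram"],
                        expected_labels = COHORT_CFG$channel_labels)
  rec$subject <- s
  rec
}

preprocessed_epochs <- function(rec) {
  ep <- extract_epochs(rec)
  ep <- screen_outliers(reject_artifacts_auto(ep))
  highpass_baseline(ep)
}
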