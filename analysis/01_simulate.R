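#!/usr/bin/env Rscript
# Generate the synthetic cohort: one polysomnography recording per subject
# (EDF + events + hypnogram + ground-truth JSON) and the behavioral table.

source("analysis/00_config.R")

behav <- list()
for (s in seq_len(N_SUBJECTS)) {
  g <- generate_recording(COHORT_CFG, s)
  write_fixture(g$recording, g$truth, FIXTURE_DIR)
  behav[[s]] <- generate_behavior(COHORT_CFG, g$truth)
  cat(sprintf(
    "subject %d: %4d cues, %3d injected SOs, %3d injected spindles, true benefit %.3f\n",
    s, nrow(g$recording$events), nrow(g$truth$so), nrow(g$truth$spindles),
    g$truth$true_benefit))
}
behav_tab <- do.call(rbind, behav)
write.csv(behav_tab, file.path(FIXTURE_DIR, "behavior_items.csv"),
          row.names = FALSE)
cat("wrote", N_SUBJECTS, "recordings and the item-level behavior table\n")
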