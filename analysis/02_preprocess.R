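#!/usr/bin/env Rscript
# Cue-locked epoching and two-step artifact rejection; logs retained trial
# counts per condition (a check that rejection does not favour a cue type).

source("analysis/00_config.R")

logs <- list()
for (s in seq_len(N_SUBJECTS)) {
  rec <- load_subject(s)
  ep <- extract_epochs(rec)
  ep <- screen_outliers(reject_artifacts_auto(ep))
  log <- rejection_log(ep)
  log$subject <- s
  logs[[s]] <- log
  cat(sprintf("subject %d: %d/%d trials retained\n", s,
              sum(log$retained), sum(log$retained) + sum(log$flagged)))
}
rej <- do.call(rbind, logs)
write.csv(rej, file.path(TABLE_DIR, "rejection_log.csv"), row.names = FALSE)
print(aggregate(cbind(retained, flagged) ~ condition, rej, sum))
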