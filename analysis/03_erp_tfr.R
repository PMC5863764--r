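#!/usr/bin/env Rscript
# Cue-locked ERPs and percent-change TFRs; contrasts old memory cues
# against control adjectives with the cluster-based permutation test
# (channel x frequency x time grid, montage adjacency).

source("analysis/00_config.R")

freqs <- seq(10, 18, by = 0.5)
tfr_old <- list(); tfr_ctl <- list(); erp_rows <- list()
for (s in seq_len(N_SUBJECTS)) {
  ep <- preprocessed_epochs(load_subject(s))
  erp <- compute_erp(ep, collapse_channels = TRUE)
  erp_rows[[s]] <- data.frame(subject = s, time = attr(erp, "times"),
                              erp_uv = as.numeric(erp))
  tfr_old[[s]] <- percent_change(compute_tfr(
    ep, freqs = freqs, step_ms = 20,
    condition = c("old-object", "old-scene")))$power
  tfr_ctl[[s]] <- percent_change(compute_tfr(
    ep, freqs = freqs, step_ms = 20, condition = "control"))$power
  cat("subject", s, "TFRs done\n")
}
write.csv(do.call(rbind, erp_rows), file.path(TABLE_DIR, "erp_grand.csv"),
          row.names = FALSE)

to_arr <- function(lst) {
  out <- array(NA_real_, dim = c(length(lst), dim(lst[[1]])))
  for (i in seq_along(lst)) out[i, , , ] <- lst[[i]]
  out
}
a <- to_arr(tfr_old); b <- to_arr(tfr_ctl)
ok_t <- apply(!is.na(a[1, 1, 1, , drop = FALSE]), 4, all) &
  apply(!is.na(b[1, 1, 1, , drop = FALSE]), 4, all)
res <- permutation_p(a[, , , ok_t], b[, , , ok_t], n_perm = 500, seed = 7,
                     channel_dim = 1,
                     channel_labels = COHORT_CFG$channel_labels,
                     channel_adjacency = montage_adjacency())
sig <- significant_clusters(res)
cat(sprintf("old vs control TFR: %d cluster(s), %d significant\n",
            length(res$clusters), length(sig)))
cl_rows <- lapply(res$clusters, function(cl) data.frame(
  polarity = cl$polarity, mass = cl$mass, p = cl$p, n_points = nrow(cl$points)))
write.csv(do.call(rbind, cl_rows), file.path(TABLE_DIR, "tfr_clusters.csv"),
          row.names = FALSE)
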