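#!/usr/bin/env Rscript
# Sliding-window representational similarity: within- vs between-category
# time courses for old cues, trial-label cluster permutation inference,
# and per-subject category distinctiveness in the 1.76-2.06 s window.

source("analysis/00_config.R")

feat_list <- list(); series_rows <- list(); dist_rows <- list()
for (s in seq_len(N_SUBJECTS)) {
  ep <- preprocessed_epochs(load_subject(s))
  fe <- build_feature_vectors(ep, step_ms = 20)
  keep <- fe$metadata$condition %in% c("old-object", "old-scene")
  fe$features <- fe$features[keep, , , drop = FALSE]
  fe$metadata <- fe$metadata[keep, , drop = FALSE]
  feat_list[[s]] <- fe
  ser <- within_between_series(fe, seed = s)
  ser$subject <- s
  series_rows[[s]] <- ser
  dist_rows[[s]] <- data.frame(
    subject = s, distinctiveness = distinctiveness(ser)$value)
  cat("subject", s, "similarity series done\n")
}
write.csv(do.call(rbind, series_rows),
          file.path(TABLE_DIR, "similarity_series.csv"), row.names = FALSE)
write.csv(do.call(rbind, dist_rows),
          file.path(TABLE_DIR, "distinctiveness.csv"), row.names = FALSE)

res <- rsa_cluster_test(feat_list, n_perm = 500, seed = 5)
times <- feat_list[[1]]$times
for (cl in res$clusters)
  cat(sprintf("cluster %s: %.2f..%.2f s, mass %.1f, p = %.4f\n",
              cl$polarity, times[min(cl$indices)], times[max(cl$indices)],
              cl$mass, cl$p))
cl_rows <- lapply(res$clusters, function(cl) data.frame(
  polarity = cl$polarity, start_s = times[min(cl$indices)],
  end_s = times[max(cl$indices)], mass = cl$mass, p = cl$p))
if (length(cl_rows))
  write.csv(do.call(rbind, cl_rows),
            file.path(TABLE_DIR, "rsa_clusters.csv"), row.names = FALSE)
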