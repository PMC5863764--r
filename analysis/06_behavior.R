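#!/usr/bin/env Rscript
# Behavioral endpoints (conditional retention, TMR benefit, discrimination
# index) and the brain-behavior correlation between category
# distinctiveness and the cueing benefit.

source("analysis/00_config.R")

items <- read.csv(file.path(FIXTURE_DIR, "behavior_items.csv"))
class(items) <- c("nap_behavior", "data.frame")
summ <- behavior_summary(items)
write.csv(summ, file.path(TABLE_DIR, "behavior_summary.csv"),
          row.names = FALSE)
cat(sprintf("mean T2->T3 retention: cued %.3f, non-cued %.3f\n",
            mean(summ$retention_t3_cued, na.rm = TRUE),
            mean(summ$retention_t3_noncued, na.rm = TRUE)))
cat(sprintf("mean TMR benefit: %.3f (+/- %.3f SEM)\n",
            mean(summ$benefit, na.rm = TRUE),
            sd(summ$benefit, na.rm = TRUE) / sqrt(sum(!is.na(summ$benefit)))))
cat(sprintf("mean discrimination index: %.3f\n",
            mean(summ$discrimination, na.rm = TRUE)))

dist <- read.csv(file.path(TABLE_DIR, "distinctiveness.csv"))
merged <- merge(dist, summ, by = "subject")
bb <- brain_behavior_correlation(merged$distinctiveness, merged$benefit)
cat(sprintf("distinctiveness vs benefit: Spearman rho = %.3f, p = %.3f (n = %d)\n",
            bb$rho, bb$p, bb$n))
write.csv(data.frame(rho = bb$rho, p = bb$p, n = bb$n),
          file.path(TABLE_DIR, "brain_behavior.csv"), row.names = FALSE)
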