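#!/usr/bin/env Rscript
# Step 3 -- pseudo-online decoding.
#
# Reuses each batch fold's spatial model, trains on jittered 2 s
# windows, slides a 2 s window over the test trials (9 epochs per
# trial), scores trials with the all-or-nothing rule for averaging
# orders m = 1, 2, 3, and writes the ROC/AUC tables and the decoder
# output time-courses.

library(gaitEEG)

if (!file.exists("results/cache/batch.rds"))
  stop("run analysis/02_batch_decode.R first (batch models are reused)")
batch <- readRDS("results/cache/batch.rds")

online <- run_pseudo_online(batch, seed = 1)
saveRDS(online, "results/cache/online.rds")
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

auc_tab <- NULL
roc_tab <- NULL
for (s in names(online$roc)) {
  for (m in 1:3) {
    r <- online$roc[[s]][[m]]
    auc_tab <- rbind(auc_tab, data.frame(subject = s, m = m, auc = r$auc))
    roc_tab <- rbind(roc_tab, data.frame(subject = s, m = m,
                                         fpr = r$fpr, tpr = r$tpr))
  }
}
write.table(auc_tab, "results/tables/online_auc.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(roc_tab, "results/tables/online_roc.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

tc_tab <- NULL
for (s in names(online$timecourse))
  tc_tab <- rbind(tc_tab, cbind(subject = s, online$timecourse[[s]]))
write.table(tc_tab, "results/tables/online_timecourse.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

message(paste(capture.output(print(auc_tab)), collapse = "\n"))
message("wrote results/tables (online_auc, online_roc, online_timecourse)")
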