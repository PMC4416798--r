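#!/usr/bin/env Rscript
# Step 1 -- generate a synthetic subject.
#
# Simulates the 10 treadmill sessions of subject 1 (7 cued, 3 uncued,
# 380 s each, 64 channels at 2048 Hz) with parietal/motor mu-beta ERD
# sources, 1/f background, blink, EMG and step-locked artifacts; writes
# the event tables and speed profiles of every session, the first
# session as a 24-bit BDF file, and a session manifest.

library(gaitEEG)

seed <- 1
out_dir <- "results/data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- default_config()
write_config(cfg, file.path(out_dir, "config.yaml"))
write_montage(montage_biosemi64(), file.path(out_dir, "montage.tsv"))

conds <- session_conditions()
manifest <- NULL
for (i in seq_along(conds)) {
  rec <- simulate_session(cfg, conds[i], seed = seed, subject = 1,
                          session_id = i)
  write_events_tsv(rec, file.path(out_dir, sprintf("session%02d_events.tsv", i)))
  write_profile_tsv(rec$profile,
                    file.path(out_dir, sprintf("session%02d_speed.tsv", i)))
  if (i == 1) write_bdf(rec, file.path(out_dir, "session01.bdf"))
  manifest <- rbind(manifest, data.frame(
    session = i, condition = conds[i], n_events = nrow(rec$events),
    duration_s = ncol(rec$data) / rec$fs,
    rms_uV = round(sqrt(mean(rec$data^2)), 2)))
  message(sprintf("session %02d (%s): %d speed-change onsets", i,
                  conds[i], nrow(rec$events)))
  rm(rec)
}
write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
message("cued sessions produce 18 onsets each; uncued timing is self-paced.")
message("wrote ", out_dir)
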