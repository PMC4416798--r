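#!/usr/bin/env Rscript
# Step 4 -- component clustering and artifact quality control.
#
# Clusters the retained independent components of all subjects and
# folds by dipole location and scalp-map principal components, projects
# the cluster centroids dorsally onto the cortex sphere, and runs the
# two artifact QC analyses: channel r^2 correlation matrices per
# walking condition, and the retained-vs-rejected ERSP pairing.

library(gaitEEG)

if (!file.exists("results/cache/batch.rds"))
  stop("run analysis/02_batch_decode.R first")
batch <- readRDS("results/cache/batch.rds")
cfg <- batch$config
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

## clustering of retained components
mem <- collect_cluster_members(batch)
cs <- cluster_components(mem, k = cfg$cluster$k,
                         outlier_sd = cfg$cluster$outlier_sd, seed = 1,
                         min_fold_frac = cfg$cluster$min_fold_frac,
                         min_subjects = cfg$cluster$min_subjects)
memb_tab <- data.frame(subject = mem$subject, fold = mem$fold,
                       component = mem$component,
                       cluster = cs$assignment,
                       x = mem$xyz[, 1], y = mem$xyz[, 2], z = mem$xyz[, 3])
write.table(memb_tab, "results/tables/cluster_members.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cent_tab <- NULL
for (i in seq_along(cs$clusters)) {
  ctr <- cs$centroid_xyz[i, ]
  proj <- project_centroid_dorsal(ctr, cfg$cluster$cortex_fraction,
                                  cfg$head$shell_radii[4])
  cent_tab <- rbind(cent_tab, data.frame(
    cluster = cs$clusters[i], x = ctr[1], y = ctr[2], z = ctr[3],
    x_dorsal = proj[1], y_dorsal = proj[2], z_dorsal = proj[3],
    n_members = sum(cs$assignment == cs$clusters[i]),
    n_subjects = length(unique(mem$subject[cs$assignment == cs$clusters[i]]))))
}
write.table(cent_tab, "results/tables/cluster_centroids.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
message(sprintf("%d clusters survived the membership rules", nrow(cent_tab)))

## channel correlation QC (subject 1, first three sessions regenerated
## at the analysis rate in the 1-45 Hz band)
spec_wide <- design_fir(cfg$preprocess$band, cfg$fs)
qc_recs <- lapply(1:3, function(i) {
  r <- simulate_session(cfg, session_conditions()[i], seed = batch$seed,
                        subject = 1, session_id = i)
  r <- apply_zero_phase(r, spec_wide)
  resample_recording(r, cfg$fs_analysis, anti_alias = FALSE)
})
qc <- channel_correlation_qc(qc_recs, cfg)
write.table(data.frame(pair = names(qc$mad), mad = qc$mad),
            "results/tables/qc_r2_mad.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
for (nm in names(qc$r2))
  write.table(qc$r2[[nm]],
              sprintf("results/tables/qc_r2_%s.tsv", nm), sep = "\t",
              row.names = FALSE, col.names = FALSE)
message(sprintf("r^2 mean absolute differences: %s",
                paste(sprintf("%s %.4f", names(qc$mad), qc$mad),
                      collapse = "; ")))

## retained vs rejected ERSP pairing (per subject, first fold)
pair_tab <- NULL
for (s_chr in names(batch$subjects)) {
  sub <- batch$subjects[[s_chr]]
  fb <- sub$cv$folds[[1]]
  sp <- fb$spatial
  rejected <- setdiff(seq_len(sp$model$n_comp), sp$candidates)
  if (length(rejected) == 0) next
  ep <- extract_batch(sub$prep$rec840[[sp$test_session]], config = cfg)
  tfc <- tf_config(fs = cfg$fs_analysis,
                   n_windows = cfg$tf$n_windows_batch)
  mk_ersp <- function(ids) {
    un <- apply_unmixing(ep, sp$model, ids)
    tf <- epochs_tf(un, tfc)
    es <- ersp(tf, "change", baseline = "preonset",
               baseline_range = c(-3.789, -1.007))
    out <- lapply(seq_along(ids), function(i) es[i, , ])
    names(out) <- as.character(ids)
    out
  }
  best <- retained_rejected_pairing(mk_ersp(fb$retained_ids),
                                    mk_ersp(rejected),
                                    sp$fits[rejected])
  pair_tab <- rbind(pair_tab, data.frame(
    subject = s_chr,
    rejected = if (is.null(best$pair)) NA else best$pair["rejected"],
    retained = if (is.null(best$pair)) NA else best$pair["retained"],
    correlation = best$correlation, n_eligible = best$n_eligible))
}
write.table(pair_tab, "results/tables/qc_retained_rejected.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
message("wrote results/tables (cluster_*, qc_*)")
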