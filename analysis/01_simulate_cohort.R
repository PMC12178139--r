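#!/usr/bin/env Rscript
# Simulate the synthetic pre/post rehabilitation cohort and write it to disk
# in the pipeline's interchange formats (matrix+sidecar EEG, ROI/atlas/
# cohort TSV), plus the ground truth needed to score every later stage.
#
# Cohort: 24 responders + 28 nonresponders, two timepoints. To keep the
# on-disk footprint and runtime of this walkthrough modest the EEG
# recordings are 60 s (the statistical conditions - SNR, dwell structure,
# effect sizes - are the generator defaults; only the recording length is
# shortened). Bulky per-subject data go under scratch/cohort/, summary
# tables under results/.

suppressMessages(library(neurostate))

seed <- 1L
out_data <- "scratch/cohort"
out_res <- "results"
dir.create(file.path(out_data, "eeg"), recursive = TRUE, showWarnings = FALSE)
dir.create(file.path(out_data, "bold"), recursive = TRUE, showWarnings = FALSE)
dir.create(out_res, recursive = TRUE, showWarnings = FALSE)

message("Simulating cohort (seed ", seed, ") ...")
co <- simulate_cohort(cohort_effects(seed = seed),
                      eeg_sim_params(duration_s = 60),
                      bold_sim_params(),
                      mode = "full")

# clinical table: ship it with groups masked; stage 04 re-derives them
cohort_out <- co$cohort
cohort_out$group <- "unknown"
write_cohort(cohort_out, file.path(out_data, "cohort.tsv"))
write_atlas(co$atlas, file.path(out_data, "atlas.tsv"))

for (nm in names(co$eeg))
  write_eeg_matrix(co$eeg[[nm]], file.path(out_data, "eeg", paste0(nm, ".tsv")))
for (nm in names(co$bold))
  write_roi_table(co$bold[[nm]], file.path(out_data, "bold", paste0(nm, ".tsv")))

# ground truth for later scoring
write_metrics_tsv(co$eeg_metrics, file.path(out_data, "truth_eeg_metrics.tsv"))
write_metrics_tsv(co$cap_metrics, file.path(out_data, "truth_cap_metrics.tsv"))
write_metrics_tsv(co$cohort, file.path(out_data, "truth_cohort.tsv"))
utils::write.table(co$templates, file.path(out_data, "truth_templates.tsv"),
                   sep = "\t", row.names = FALSE, col.names = FALSE)

n_eeg <- length(co$eeg)
message(sprintf("Wrote %d EEG recordings and %d ROI tables for %d subjects.",
                n_eeg, length(co$bold), nrow(co$cohort) / 2))
message("True responder rate: ",
        round(100 * mean(co$cohort$group == "responder"), 1), "%")
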