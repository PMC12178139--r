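#!/usr/bin/env Rscript
# Prediction stage: assemble the four baseline features (MDS-UPDRS III
# total, microstate C and D occurrence, DAN+ VAN- dwell time), and compare
# clinical / EEG / fMRI / multimodal feature sets with a nested
# cross-validated SVM under shared splits.

suppressMessages(library(neurostate))

seed <- 5L
data_dir <- "scratch/cohort"
dir.create("results", showWarnings = FALSE)

cohort <- stratify_responders(read_cohort(file.path(data_dir, "cohort.tsv")))
ms <- utils::read.delim("results/microstate_metrics.tsv")
cm <- utils::read.delim("results/cap_metrics.tsv")

pre_ms <- ms[ms$timepoint == "pre", ]
eeg_feat <- data.frame(
  subject_id = unique(pre_ms$subject_id),
  ms_C_occurrence = pre_ms$occurrence[pre_ms$state == "C"],
  ms_D_occurrence = pre_ms$occurrence[pre_ms$state == "D"])
dan_cap <- grep("^DAN\\+ VAN-$", unique(cm$cap), value = TRUE)[1]
pre_cm <- cm[cm$timepoint == "pre" & cm$cap == dan_cap, ]
cap_feat <- data.frame(subject_id = pre_cm$subject_id,
                       cap_DANpVANm_dwell = pre_cm$dwell_time_s)

ft <- build_feature_table(eeg_feat, cap_feat, cohort)
message("Feature table: ", nrow(ft), " subjects",
        if (length(attr(ft, "excluded")))
          paste0(" (excluded: ", paste(attr(ft, "excluded"), collapse = ", "), ")")
        else "")

cmp <- suppressWarnings(
  compare_feature_sets(ft, repetitions = 5, seed = seed, kernel = "linear",
                       grid_size = 5))

tab <- do.call(rbind, lapply(names(cmp$reports), function(nm) {
  s <- cmp$reports[[nm]]$summary
  data.frame(feature_set = nm,
             accuracy = sprintf("%.2f +/- %.2f", s$mean[1], s$se[1]),
             sensitivity = sprintf("%.2f +/- %.2f", s$mean[2], s$se[2]),
             specificity = sprintf("%.2f +/- %.2f", s$mean[3], s$se[3]))
}))
write_metrics_tsv(tab, "results/prediction_report.tsv")

message("Responder prediction, 5 x 5-fold nested CV, 5 iterations (mean +/- SE %):")
for (i in order(-vapply(cmp$reports, function(r) r$summary$mean[1], 0))) {
  message(sprintf("  %-10s acc %s  sens %s  spec %s", tab$feature_set[i],
                  tab$accuracy[i], tab$sensitivity[i], tab$specificity[i]))
}
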