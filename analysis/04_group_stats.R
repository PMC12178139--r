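#!/usr/bin/env Rscript
# Group statistics stage: stratify responders by the 3.25-point MCID rule,
# run the 2x2 mixed ANOVA (group x time) with partial eta squared on every
# microstate and CAP metric, follow significant interactions with
# Bonferroni-corrected simple effects, and correlate clinical reduction
# rates with neural change rates (Spearman, Bonferroni).

suppressMessages(library(neurostate))

data_dir <- "scratch/cohort"
dir.create("results", showWarnings = FALSE)

cohort <- stratify_responders(read_cohort(file.path(data_dir, "cohort.tsv")))
s <- attr(cohort, "summary")
message(sprintf("Stratification: %d responders / %d nonresponders (%.1f%%)",
                s$n_responders, s$n_nonresponders, s$responder_pct))

ms <- utils::read.delim("results/microstate_metrics.tsv")
cm <- utils::read.delim("results/cap_metrics.tsv")
grp <- cohort$group[match(ms$subject_id, cohort$subject_id)]
ms$group <- grp
cm$group <- cohort$group[match(cm$subject_id, cohort$subject_id)]

anova_block <- function(df, value_col, label_col) {
  out <- list()
  for (lv in unique(df[[label_col]])) {
    v <- df[df[[label_col]] == lv, ]
    a <- mixed_anova_2x2(v[[value_col]], v$group, v$timepoint, v$subject_id)
    out[[lv]] <- cbind(metric = paste0(value_col, "[", lv, "]"), a)
  }
  do.call(rbind, out)
}

res <- rbind(
  anova_block(ms, "occurrence", "state"),
  anova_block(ms, "coverage", "state"),
  anova_block(ms, "duration_ms", "state"),
  anova_block(cm, "dwell_time_s", "cap"),
  anova_block(cm, "fractional_occupancy", "cap"),
  anova_block(cm, "appearance_rate_per_min", "cap"))
write_metrics_tsv(res, "results/group_anova.tsv")

sig <- res[res$effect == "group:time" & res$p < 0.05, ]
message("Significant group x time interactions (uncorrected p < 0.05):")
for (i in seq_len(nrow(sig)))
  message(sprintf("  %-28s F(%d,%d) = %6.2f, p = %.4f, eta_p2 = %.3f",
                  sig$metric[i], sig$df1[i], sig$df2[i], sig$F[i],
                  sig$p[i], sig$eta_p2[i]))

# simple effects for the flagged metrics
se_rows <- list()
for (m in sig$metric) {
  col <- sub("\\[.*", "", m); lv <- sub(".*\\[(.*)\\]", "\\1", m)
  df <- if (col %in% names(ms)) ms else cm
  lab <- if (col %in% names(ms)) "state" else "cap"
  v <- df[df[[lab]] == lv, ]
  se <- simple_effects(v[[col]], v$group, v$timepoint, v$subject_id)
  se_rows[[m]] <- cbind(metric = m, se)
}
if (length(se_rows))
  write_metrics_tsv(do.call(rbind, se_rows), "results/simple_effects.tsv")

# clinical correlation of change rates (responding metrics vs MDS-UPDRS III)
wide <- function(df, col, lab, lv) {
  v <- df[df[[lab]] == lv, ]
  pre <- v[v$timepoint == "pre", ]; post <- v[v$timepoint == "post", ]
  post <- post[match(pre$subject_id, post$subject_id), ]
  data.frame(subject_id = pre$subject_id,
             rate = change_rate(pre[[col]], post[[col]], type = "change"))
}
cl_pre <- cohort[cohort$timepoint == "pre", ]
cl_post <- cohort[cohort$timepoint == "post", ]
cl_post <- cl_post[match(cl_pre$subject_id, cl_post$subject_id), ]
clin <- data.frame(subject_id = cl_pre$subject_id,
                   updrs_reduction = change_rate(cl_pre$mds_updrs3_total,
                                                 cl_post$mds_updrs3_total))
occ_c <- wide(ms, "occurrence", "state", "C")
occ_d <- wide(ms, "occurrence", "state", "D")
dan_cap <- grep("^DAN\\+ VAN-$", unique(cm$cap), value = TRUE)
dw <- wide(cm, "dwell_time_s", "cap", dan_cap[1])
x <- data.frame(ms_C_occurrence_change = occ_c$rate[match(clin$subject_id, occ_c$subject_id)],
                ms_D_occurrence_change = occ_d$rate[match(clin$subject_id, occ_d$subject_id)],
                cap_DANpVANm_dwell_change = dw$rate[match(clin$subject_id, dw$subject_id)])
corr <- spearman_family(x, clin["updrs_reduction"], family_size = 3)
write_metrics_tsv(corr, "results/clinical_correlations.tsv")
message("Spearman change-rate correlations with MDS-UPDRS III reduction rate:")
for (i in seq_len(nrow(corr)))
  message(sprintf("  %-28s rho = %+.3f, p = %.4f, p_bonf = %.4f",
                  corr$x_var[i], corr$rho[i], corr$p[i], corr$p_bonferroni[i]))
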