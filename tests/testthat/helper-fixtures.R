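# Shared fixture builders. Everything is generated in code; no files ship
# with the tests.

# a tiny deterministic recording built from one or more template rows
rec_from_templates <- function(templates, states, seg_ms, fs = 500,
                               amplitude = 1) {
  stopifnot(length(states) == length(seg_ms))
  lens <- round(seg_ms * fs / 1000)
  x <- do.call(cbind, lapply(seq_along(states), function(i)
    outer(templates[states[i], ], rep(amplitude, lens[i]))))
  eeg_recording(x, fs = fs)
}

# null cohort configuration: no injected effects anywhere
null_effects <- function(seed, n_r = 8, n_n = 8) {
  cohort_effects(n_responders = n_r, n_nonresponders = n_n,
                 occurrence_C_factor = 1, occurrence_D_factor = 1,
                 transition_AB_to_D_boost = 0,
                 dwell_DANpVANm_factor = 1,
                 baseline_occurrence_C_factor = 1,
                 baseline_occurrence_D_factor = 1,
                 baseline_dwell_DANpVANm_factor = 1,
                 coupling_rho = 0, seed = seed)
}

# baseline (pre) feature table from a simulated cohort's ground truth
cohort_feature_table <- function(co) {
  em <- co$eeg_metrics[co$eeg_metrics$timepoint == "pre", ]
  c3 <- em[em$state == 3, ]; c4 <- em[em$state == 4, ]
  ms <- data.frame(subject_id = c3$subject_id,
                   ms_C_occurrence = c3$occurrence,
                   ms_D_occurrence = c4$occurrence[match(c3$subject_id,
                                                         c4$subject_id)])
  cm <- co$cap_metrics[co$cap_metrics$timepoint == "pre" &
                         co$cap_metrics$state == 1, ]
  cb <- data.frame(subject_id = cm$subject_id,
                   cap_DANpVANm_dwell = cm$dwell_time_s)
  build_feature_table(ms, cb, co$cohort)
}

# two-class Gaussian feature table with programmable separation d'
gaussian_features <- function(n = 50, d = 6, p = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n1 <- n %/% 2; n2 <- n - n1
  X <- rbind(matrix(stats::rnorm(n1 * p), n1),
             matrix(stats::rnorm(n2 * p, mean = d / sqrt(p)), n2))
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(p))
  df$label <- factor(rep(c("nonresponder", "responder"), c(n1, n2)),
                     levels = c("nonresponder", "responder"))
  df
}
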