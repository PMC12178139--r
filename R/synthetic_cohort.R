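# Full synthetic pre/post cohort: microstate-structured EEG, CAP-structured
# ROI BOLD and coupled clinical scores, with ground truth stored for every
# simulated quantity.

#' Cohort-level effect configuration for the synthetic generator
#'
#' Encodes the group sizes, the injected post-intervention neural effects
#' (responders get the stated factors, nonresponders their reciprocals), the
#' baseline group differences carried by the prediction features, the
#' clinical score moments, and the Gaussian-copula coupling between clinical
#' improvement and neural change.
#'
#' @param n_responders,n_nonresponders group sizes (default 24 / 28).
#' @param occurrence_C_factor,occurrence_D_factor responder post/pre
#'   multipliers of microstate C and D occurrence (defaults 0.8, 1.25).
#' @param transition_AB_to_D_boost guaranteed minimum absolute increase of
#'   the A->D and B->D transition probabilities in responders post
#'   (decrease in nonresponders; default 0.05).
#' @param dwell_DANpVANm_factor responder post/pre multiplier of the
#'   "DAN+ VAN-" CAP dwell time (default 1.3).
#' @param baseline_occurrence_C_factor,baseline_occurrence_D_factor,baseline_dwell_DANpVANm_factor
#'   responder-vs-nonresponder baseline differences carrying the
#'   predictive signal. Responders start with slightly raised microstate C
#'   and lowered microstate D occurrence (defaults 1.16 and 0.86; opposite
#'   directions keep the shared duration jitter off the C/D discriminant
#'   and avoid simplex attenuation) and a longer "DAN+ VAN-" dwell
#'   (default 1.6, sized against the ~50% sampling noise a 240-frame run
#'   puts on a per-subject dwell estimate).
#' @param subject_sd log-normal SD of per-subject jitter on state weights
#'   and effect factors (default 0.12).
#' @param coupling_rho magnitude of the latent Gaussian correlation between
#'   clinical improvement and each neural effect (default 0.4; must be in
#'   `[0, 1]`). Signs are fixed: C negative, D positive, dwell positive.
#' @param equalize_baseline_clinical draw pre clinical scores from pooled
#'   (group-independent) moments so only neural features carry baseline
#'   signal (default FALSE).
#' @param seed RNG seed for the whole cohort draw.
#' @return list of class `cohort_effects`.
#' @export
cohort_effects <- function(n_responders = 24, n_nonresponders = 28,
                           occurrence_C_factor = 0.8,
                           occurrence_D_factor = 1.25,
                           transition_AB_to_D_boost = 0.05,
                           dwell_DANpVANm_factor = 1.3,
                           baseline_occurrence_C_factor = 1.16,
                           baseline_occurrence_D_factor = 0.86,
                           baseline_dwell_DANpVANm_factor = 1.6,
                           subject_sd = 0.12,
                           coupling_rho = 0.4,
                           equalize_baseline_clinical = FALSE,
                           seed = NULL) {
  if (n_responders < 2 || n_nonresponders < 2)
    ns_stop("neurostate_error_group_size", "group sizes must be >= 2")
  for (f in c(occurrence_C_factor, occurrence_D_factor, dwell_DANpVANm_factor,
              baseline_occurrence_C_factor, baseline_occurrence_D_factor,
              baseline_dwell_DANpVANm_factor))
    if (f <= 0) ns_stop("neurostate_error_bad_factor", "factors must be positive")
  if (abs(coupling_rho) > 1)
    ns_stop("neurostate_error_bad_coupling", "|coupling_rho| must be <= 1")
  structure(list(
    n_responders = n_responders, n_nonresponders = n_nonresponders,
    occurrence_C_factor = occurrence_C_factor,
    occurrence_D_factor = occurrence_D_factor,
    transition_AB_to_D_boost = transition_AB_to_D_boost,
    dwell_DANpVANm_factor = dwell_DANpVANm_factor,
    baseline_occurrence_C_factor = baseline_occurrence_C_factor,
    baseline_occurrence_D_factor = baseline_occurrence_D_factor,
    baseline_dwell_DANpVANm_factor = baseline_dwell_DANpVANm_factor,
    subject_sd = subject_sd, coupling_rho = coupling_rho, seed = seed,
    clinical = clinical_moments(equalize_baseline_clinical)),
    class = "cohort_effects")
}

# Per-group pre-score moments and pre-minus-post change moments, on the
# MDS-UPDRS III scale. Subscale change SDs are set so their variances sum
# approximately to the total-change variance implied by the reported paired
# tests. With equalize_baseline = TRUE both groups draw their pre scores
# from the pooled moments (no baseline clinical signal), leaving only the
# change moments group-specific.
clinical_moments <- function(equalize_baseline = FALSE) {
  m <- list(
    responder = list(
      tremor = c(pre_mean = 4.21, pre_sd = 3.93, ch_mean = 0.67, ch_sd = 1.3),
      bradykinesia = c(19.92, 7.23, 4.46, 2.4),
      rigidity = c(9.75, 2.19, 0.42, 0.7),
      axial = c(6.54, 3.68, 1.08, 1.2),
      pdq39 = c(23.60, 9.92, 8.43, 3.3),
      total_change = c(mean = 6.63, sd = 3.08, lo = 3.5, hi = Inf)),
    nonresponder = list(
      tremor = c(pre_mean = 3.50, pre_sd = 3.67, ch_mean = -0.50, ch_sd = 1.2),
      bradykinesia = c(18.71, 6.14, -0.22, 2.0),
      rigidity = c(8.75, 1.82, -0.39, 0.7),
      axial = c(5.29, 2.57, 0.25, 0.9),
      pdq39 = c(24.19, 8.85, 3.70, 3.0),
      total_change = c(mean = -0.86, sd = 3.50, lo = -Inf, hi = 3.25)))
  if (equalize_baseline) {
    for (sc in c("tremor", "bradykinesia", "rigidity", "axial", "pdq39")) {
      pooled <- (m$responder[[sc]][1:2] + m$nonresponder[[sc]][1:2]) / 2
      m$responder[[sc]][1:2] <- pooled
      m$nonresponder[[sc]][1:2] <- pooled
    }
  }
  m
}

# truncated-normal inverse CDF (rank-preserving, for the copula)
qtnorm <- function(u, mean, sd, lo = -Inf, hi = Inf) {
  plo <- stats::pnorm(lo, mean, sd); phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + u * (phi - plo), mean, sd)
}

rtnorm1 <- function(mean, sd, lo = 0) qtnorm(stats::runif(1), mean, sd, lo = lo)

#' Calibrate a zero-diagonal jump matrix to a target visit distribution
#'
#' Finds destination weights w such that the jump chain
#' P(i -> j) = w_j / sum_{l != i} w_l has stationary distribution
#' `target_pi`, by fixed-point iteration.
#'
#' @param target_pi desired stationary distribution of the jump chain.
#' @param n_iter fixed-point iterations (default 80).
#' @return zero-diagonal row-stochastic matrix.
#' @export
calibrate_jump_matrix <- function(target_pi, n_iter = 80) {
  k <- length(target_pi)
  target_pi <- target_pi / sum(target_pi)
  w <- target_pi
  for (it in seq_len(n_iter)) {
    P <- jump_from_weights(w)
    pi_cur <- stationary_dist(P)
    if (max(abs(pi_cur - target_pi)) < 1e-12) break
    w <- w * target_pi / pmax(pi_cur, 1e-12)
    w <- w / sum(w)
  }
  jump_from_weights(w)
}

jump_from_weights <- function(w) {
  k <- length(w)
  P <- matrix(w, k, k, byrow = TRUE)
  diag(P) <- 0
  P / rowSums(P)
}

stationary_dist <- function(P) {
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v / sum(v)
}

# enforce a minimum absolute change of the A->D / B->D entries relative to
# the pre matrix (rows 1 and 2, column `to`), renormalising the other
# off-diagonal entries
enforce_transition_boost <- function(P_post, P_pre, boost, to = 4L) {
  for (r in 1:2) {
    target <- if (boost >= 0) max(P_post[r, to], P_pre[r, to] + boost)
              else min(P_post[r, to], max(P_pre[r, to] + boost, 0))
    target <- min(max(target, 0), 0.98)
    others <- setdiff(seq_len(ncol(P_post)), c(r, to))
    rest <- sum(P_post[r, others])
    P_post[r, others] <- P_post[r, others] * (1 - target) / rest
    P_post[r, to] <- target
  }
  P_post
}

#' Simulate a full pre/post cohort with ground truth
#'
#' Draws one subject at a time: a semi-Markov microstate state sequence and
#' (optionally) the EEG waveform for each timepoint, a Markov CAP state
#' sequence and (optionally) the ROI BOLD table, and integer clinical
#' scores. Responders' post-intervention dynamics use the configured effect
#' factors, nonresponders their reciprocals; responders' total MDS-UPDRS III
#' reduction is forced above the 3.25-point minimal clinically important
#' difference and nonresponders' below it. Clinical change and the
#' subject-level neural effect sizes share a Gaussian copula at
#' `coupling_rho`.
#'
#' @param effects a [cohort_effects()].
#' @param eeg_params an [eeg_sim_params()] (per subject x timepoint).
#' @param bold_params a [bold_sim_params()].
#' @param mode `"full"` simulates waveforms and BOLD tables; `"metrics"`
#'   draws only the state sequences and clinical scores (fast path for
#'   statistical calibration).
#' @return list with `cohort` (clinical data.frame, truth group labels),
#'   `eeg_metrics`, `eeg_transitions`, `cap_metrics` (long data.frames of
#'   realized ground-truth metrics), `templates`, `cap_patterns`, `atlas`,
#'   `eeg` and `bold` (named lists `"<subject>_<timepoint>"`, full mode
#'   only), and `subject_params`.
#' @export
simulate_cohort <- function(effects = cohort_effects(),
                            eeg_params = eeg_sim_params(),
                            bold_params = bold_sim_params(),
                            mode = c("full", "metrics")) {
  mode <- match.arg(mode)
  stopifnot(inherits(effects, "cohort_effects"))
  if (!is.null(effects$seed)) set.seed(effects$seed)
  n_r <- effects$n_responders; n_n <- effects$n_nonresponders
  n <- n_r + n_n
  ids <- sprintf("S%02d", seq_len(n))
  groups <- rep(c("responder", "nonresponder"), c(n_r, n_n))
  templates <- make_canonical_templates(eeg_params$n_channels)
  atlas <- make_atlas(bold_params$n_rois)
  cap_patterns <- make_cap_patterns(atlas)
  sj <- effects$subject_sd
  rho <- effects$coupling_rho
  k_eeg <- eeg_params$n_states
  k_cap <- bold_params$n_states
  cohort <- NULL; eeg_list <- list(); bold_list <- list()
  ms_rows <- list(); tr_rows <- list(); cap_rows <- list(); sp_rows <- list()
  for (i in seq_len(n)) {
    resp <- groups[i] == "responder"
    mom <- effects$clinical[[groups[i]]]
    # --- latent copula draws -------------------------------------------
    z_clin <- stats::rnorm(1)
    mix <- function(sign) sign * rho * z_clin + sqrt(1 - rho^2) * stats::rnorm(1)
    z_C <- mix(-1); z_D <- mix(+1); z_dw <- mix(+1)
    # --- EEG state parameters ------------------------------------------
    w_pre <- exp(stats::rnorm(k_eeg, 0, sj) - sj^2 / 2)
    if (resp) {
      w_pre[3] <- w_pre[3] * effects$baseline_occurrence_C_factor
      w_pre[4] <- w_pre[4] * effects$baseline_occurrence_D_factor
    }
    lj <- function(z) exp(sj * z - sj^2 / 2)
    m_C <- if (resp) effects$occurrence_C_factor * lj(z_C)
           else lj(z_C) / effects$occurrence_C_factor
    m_D <- if (resp) effects$occurrence_D_factor * lj(z_D)
           else lj(z_D) / effects$occurrence_D_factor
    w_post <- w_pre; w_post[3] <- w_post[3] * m_C; w_post[4] <- w_post[4] * m_D
    P_pre <- calibrate_jump_matrix(w_pre / sum(w_pre))
    P_post <- calibrate_jump_matrix(w_post / sum(w_post))
    boost <- if (resp) effects$transition_AB_to_D_boost else -effects$transition_AB_to_D_boost
    P_post <- enforce_transition_boost(P_post, P_pre, boost, to = 4L)
    dur_ms <- eeg_params$mean_duration_ms * exp(stats::rnorm(1, 0, 0.1) - 0.005)
    dur_ms <- pmax(dur_ms, 30)
    # --- CAP dwell parameters ------------------------------------------
    dw_pre <- effects_dwell_base(k_cap, bold_params$mean_dwell_frames, sj)
    if (resp) dw_pre[1] <- dw_pre[1] * effects$baseline_dwell_DANpVANm_factor
    m_dw <- if (resp) effects$dwell_DANpVANm_factor * lj(z_dw)
            else lj(z_dw) / effects$dwell_DANpVANm_factor
    dw_post <- dw_pre; dw_post[1] <- max(1.2, dw_post[1] * m_dw)
    # --- simulate both timepoints --------------------------------------
    for (tp in c("pre", "post")) {
      P <- if (tp == "pre") P_pre else P_post
      dw <- if (tp == "pre") dw_pre else dw_post
      ep <- eeg_params; ep$mean_duration_ms <- dur_ms; ep$seed <- NULL
      n_samp <- as.integer(round(ep$duration_s * ep$fs))
      if (mode == "full") {
        sub <- simulate_eeg_subject(ep, templates, P)
        sub$recording$subject_id <- ids[i]; sub$recording$timepoint <- tp
        eeg_list[[paste0(ids[i], "_", tp)]] <- sub$recording
        eeg_labels <- sub$truth$labels
      } else {
        eeg_labels <- draw_semi_markov(n_samp, ep$fs, P, dur_ms,
                                       ep$duration_shape)$labels
      }
      em <- metrics_from_labels(eeg_labels, ep$fs, k_eeg)
      ms_rows[[length(ms_rows) + 1L]] <-
        cbind(subject_id = ids[i], group = groups[i], timepoint = tp,
              em$per_state)
      tr <- em$transition
      tr_rows[[length(tr_rows) + 1L]] <-
        data.frame(subject_id = ids[i], group = groups[i], timepoint = tp,
                   from = rep(seq_len(k_eeg), k_eeg),
                   to = rep(seq_len(k_eeg), each = k_eeg),
                   prob = as.vector(tr))
      chain <- make_cap_chain(k_cap, dw)
      bp <- bold_params; bp$seed <- NULL; bp$mean_dwell_frames <- dw
      if (mode == "full") {
        bs <- simulate_bold_subject(bp, cap_patterns, chain)
        bs$table$subject_id <- ids[i]; bs$table$timepoint <- tp
        bold_list[[paste0(ids[i], "_", tp)]] <- bs$table
        cap_labels <- bs$truth$labels
      } else {
        cap_labels <- integer(bp$n_frames)
        cap_labels[1] <- sample.int(k_cap, 1)
        for (t in 2:bp$n_frames)
          cap_labels[t] <- sample.int(k_cap, 1, prob = chain[cap_labels[t - 1], ])
      }
      cm <- cap_temporal_metrics(cap_labels, tr = bold_params$tr, k = k_cap)
      cap_rows[[length(cap_rows) + 1L]] <-
        cbind(subject_id = ids[i], group = groups[i], timepoint = tp,
              cap = cap_pattern_library()$name, cm)
    }
    # --- clinical scores ------------------------------------------------
    tc <- mom$total_change
    change_total <- qtnorm(stats::pnorm(z_clin), tc["mean"], tc["sd"],
                           tc["lo"], tc["hi"])
    scores <- draw_clinical_scores(mom, change_total, resp)
    cohort <- rbind(cohort,
                    data.frame(subject_id = ids[i], group = groups[i],
                               timepoint = c("pre", "post"),
                               mds_updrs3_total = scores$total,
                               tremor = scores$tremor,
                               bradykinesia = scores$bradykinesia,
                               rigidity = scores$rigidity,
                               axial = scores$axial, pdq39 = scores$pdq39))
    sp_rows[[i]] <- data.frame(subject_id = ids[i], group = groups[i],
                               z_clin = z_clin, m_C = m_C, m_D = m_D,
                               m_dwell = m_dw, change_total = change_total)
  }
  validate_cohort(cohort)
  out <- list(cohort = cohort,
              eeg_metrics = do.call(rbind, ms_rows),
              eeg_transitions = do.call(rbind, tr_rows),
              cap_metrics = do.call(rbind, cap_rows),
              subject_params = do.call(rbind, sp_rows),
              templates = templates, cap_patterns = cap_patterns,
              atlas = atlas, effects = effects,
              eeg_params = eeg_params, bold_params = bold_params)
  if (mode == "full") {
    out$eeg <- eeg_list
    out$bold <- bold_list
  }
  out
}

effects_dwell_base <- function(k, base, sj) {
  rep_len(base, k) * exp(stats::rnorm(k, 0, 0.1) - 0.005)
}

# draw integer clinical scores for one subject given the total change
draw_clinical_scores <- function(mom, change_total, resp) {
  sub_names <- c("tremor", "bradykinesia", "rigidity", "axial")
  pre <- vapply(sub_names, function(s)
    max(0, round(rtnorm1(mom[[s]][1], mom[[s]][2], lo = 0))), 0)
  ch_means <- vapply(sub_names, function(s) mom[[s]][3], 0)
  prop <- ch_means / sum(ch_means)
  e <- stats::rnorm(4, 0, vapply(sub_names, function(s) mom[[s]][4], 0))
  e <- e - mean(e)
  delta <- change_total * prop + e
  d_int <- round(delta)
  d_int[2] <- d_int[2] + (round(change_total) - sum(d_int))  # preserve sum
  post <- pre - d_int
  # clamp into range, absorbing adjustments on bradykinesia
  for (j in seq_along(post)) if (post[j] < 0) { d_int[2] <- d_int[2] - post[j]; post[j] <- 0 }
  post[2] <- pre[2] - d_int[2]
  if (post[2] < 0) { post[2] <- 0; d_int[2] <- pre[2] }
  tot_pre <- sum(pre); tot_post <- sum(post)
  red <- tot_pre - tot_post
  # guarantee the MCID side of the stratification rule
  if (resp && red < 4) { post[2] <- max(0, post[2] - (4 - red)) }
  if (!resp && red > 3) { post[2] <- post[2] + (red - 3) }
  tot_post <- sum(post)
  pdq_pre <- max(0, round(rtnorm1(mom$pdq39[1], mom$pdq39[2], lo = 0)))
  pdq_post <- max(0, round(pdq_pre - stats::rnorm(1, mom$pdq39[3], mom$pdq39[4])))
  list(total = c(tot_pre, tot_post), tremor = c(pre[1], post[1]),
       bradykinesia = c(pre[2], post[2]), rigidity = c(pre[3], post[3]),
       axial = c(pre[4], post[4]), pdq39 = c(pdq_pre, pdq_post))
}
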