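# Markov CAP-structured ROI BOLD simulator with stored ground truth.

#' Parameters for the synthetic ROI BOLD generator
#'
#' Defaults emulate the fMRI substrate of the CAP stage: 100 ROIs over the
#' seven canonical networks, 240 frames at TR = 2 s, 14 CAP states with a
#' mean dwell of 4 frames.
#'
#' @param n_rois number of ROIs (>= 7 so each network is non-empty).
#' @param n_frames number of BOLD frames (>= 30).
#' @param tr repetition time in seconds (default 2).
#' @param n_states number of CAP states (default 14).
#' @param mean_dwell_frames mean dwell per state in frames (scalar or
#'   per-state vector; > 1).
#' @param noise_sd per-ROI Gaussian noise SD (default 0.5).
#' @param amplitude pattern amplitude multiplying the unit-norm CAP vector
#'   (default 6, deflecting each active ROI by roughly two noise SDs, the
#'   order of typical z-scored CAP deflections).
#' @param seed optional RNG seed.
#' @return list of class `bold_sim_params`.
#' @export
bold_sim_params <- function(n_rois = 100, n_frames = 240, tr = 2,
                            n_states = 14, mean_dwell_frames = 4,
                            noise_sd = 0.5, amplitude = 6, seed = NULL) {
  if (n_rois < 7)
    ns_stop("neurostate_error_too_few_rois", "need >= 7 ROIs")
  if (n_frames < 30)
    ns_stop("neurostate_error_too_few_frames", "need >= 30 frames")
  mean_dwell_frames <- rep_len(mean_dwell_frames, n_states)
  if (any(mean_dwell_frames <= 1))
    ns_stop("neurostate_error_bad_dwell", "mean dwell must exceed 1 frame")
  structure(list(n_rois = n_rois, n_frames = n_frames, tr = tr,
                 n_states = n_states, mean_dwell_frames = mean_dwell_frames,
                 noise_sd = noise_sd, amplitude = amplitude, seed = seed),
            class = "bold_sim_params")
}

#' Markov chain over CAP states with prescribed mean dwell
#'
#' Self-transition probability of state s is `1 - 1/dwell_s`; the remaining
#' mass is spread uniformly over the other states.
#'
#' @param n_states number of states.
#' @param mean_dwell_frames mean dwell in frames (scalar or per-state).
#' @return row-stochastic n x n matrix.
#' @export
make_cap_chain <- function(n_states = 14, mean_dwell_frames = 4) {
  dw <- rep_len(mean_dwell_frames, n_states)
  P <- matrix(0, n_states, n_states)
  for (s in seq_len(n_states)) {
    stay <- 1 - 1 / dw[s]
    P[s, ] <- (1 - stay) / (n_states - 1)
    P[s, s] <- stay
  }
  P
}

#' Simulate one subject's CAP-structured ROI BOLD run
#'
#' Frame t is the active CAP pattern scaled by `amplitude` plus independent
#' Gaussian noise per ROI; states follow the supplied Markov `chain`.
#' Identical parameters and seed give bit-identical output.
#'
#' @param params a [bold_sim_params()].
#' @param cap_patterns k x ROIs pattern matrix (default
#'   [make_cap_patterns()] on [make_atlas()] with `params$n_rois`).
#' @param chain row-stochastic k x k matrix (default [make_cap_chain()]
#'   from `params`).
#' @return list with `table` (a [roi_timeseries()]), `truth` (patterns,
#'   chain, per-frame labels, params) and `atlas`.
#' @export
simulate_bold_subject <- function(params, cap_patterns = NULL, chain = NULL) {
  stopifnot(inherits(params, "bold_sim_params"))
  atlas <- make_atlas(params$n_rois)
  if (is.null(cap_patterns)) cap_patterns <- make_cap_patterns(atlas)
  if (nrow(cap_patterns) != params$n_states ||
      ncol(cap_patterns) != params$n_rois)
    ns_stop("neurostate_error_pattern_dim",
            "cap_patterns must be %d x %d", params$n_states, params$n_rois)
  if (is.null(chain))
    chain <- make_cap_chain(params$n_states, params$mean_dwell_frames)
  if (any(chain < 0) || any(abs(rowSums(chain) - 1) > 1e-8))
    ns_stop("neurostate_error_not_stochastic", "chain rows must sum to 1")
  if (!is.null(params$seed)) set.seed(params$seed)
  k <- params$n_states
  labels <- integer(params$n_frames)
  labels[1] <- sample.int(k, 1)
  for (t in 2:params$n_frames)
    labels[t] <- sample.int(k, 1, prob = chain[labels[t - 1], ])
  X <- cap_patterns[labels, , drop = FALSE] * params$amplitude +
    matrix(stats::rnorm(params$n_frames * params$n_rois, sd = params$noise_sd),
           params$n_frames, params$n_rois)
  tab <- roi_timeseries(X, tr = params$tr, roi_ids = names(atlas))
  list(table = tab,
       truth = list(patterns = cap_patterns, chain = chain,
                    labels = labels, params = params),
       atlas = atlas)
}
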