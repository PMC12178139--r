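# Semi-Markov microstate EEG simulator with stored ground truth.

#' Parameters for the synthetic EEG generator
#'
#' Defaults emulate the acquisition the pipeline targets: three minutes of
#' closed-eye resting EEG at 500 Hz, band-limited 1-30 Hz, four microstate
#' classes with ~80 ms mean dwell episodes.
#'
#' @param n_channels number of channels (>= 8; default 32).
#' @param fs sampling rate in Hz (default 500).
#' @param duration_s recording length in seconds (default 180;
#'   `duration_s * fs` must be an integer).
#' @param n_states number of microstate classes (default 4).
#' @param mean_duration_ms mean state dwell per state, ms (scalar or length
#'   `n_states`; >= 30; default 80).
#' @param duration_shape gamma shape of the dwell distribution (default 4).
#' @param gfp_carrier_hz frequency of the rectified-sinusoid GFP envelope
#'   (default 10 Hz).
#' @param snr_db ratio of signal GFP power to noise GFP power, in dB
#'   (default 5).
#' @param seed optional RNG seed.
#' @return list of class `eeg_sim_params`.
#' @export
eeg_sim_params <- function(n_channels = 32, fs = 500, duration_s = 180,
                           n_states = 4, mean_duration_ms = 80,
                           duration_shape = 4, gfp_carrier_hz = 10,
                           snr_db = 5, seed = NULL) {
  if (n_channels < 8)
    ns_stop("neurostate_error_too_few_channels", "n_channels must be >= 8")
  if (abs(duration_s * fs - round(duration_s * fs)) > 1e-9)
    ns_stop("neurostate_error_bad_duration", "duration_s * fs must be integer")
  mean_duration_ms <- rep_len(mean_duration_ms, n_states)
  if (any(mean_duration_ms < 30))
    ns_stop("neurostate_error_short_duration", "mean durations must be >= 30 ms")
  structure(list(n_channels = n_channels, fs = fs, duration_s = duration_s,
                 n_states = n_states, mean_duration_ms = mean_duration_ms,
                 duration_shape = duration_shape,
                 gfp_carrier_hz = gfp_carrier_hz, snr_db = snr_db,
                 seed = seed),
            class = "eeg_sim_params")
}

check_jump_matrix <- function(P, k) {
  P <- as.matrix(P)
  if (nrow(P) != k || ncol(P) != k)
    ns_stop("neurostate_error_bad_transition", "transition matrix must be %dx%d", k, k)
  if (any(abs(diag(P)) > 1e-12))
    ns_stop("neurostate_error_diagonal_mass",
            "segment-level transition matrix must have a zero diagonal")
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-8))
    ns_stop("neurostate_error_not_stochastic", "transition rows must sum to 1")
  P
}

# draw a semi-Markov state sequence covering n_samples
draw_semi_markov <- function(n_samples, fs, P, mean_duration_ms, shape) {
  k <- nrow(P)
  cap <- as.integer(2 * n_samples / (min(mean_duration_ms) * fs / 1000) + 16)
  states <- integer(cap); lens <- integer(cap)
  s <- sample.int(k, 1)
  total <- 0L; m <- 0L
  while (total < n_samples) {
    ms <- stats::rgamma(1, shape = shape, scale = mean_duration_ms[s] / shape)
    len <- max(1L, as.integer(round(ms * fs / 1000)))
    len <- min(len, n_samples - total)
    m <- m + 1L
    if (m > length(states)) { length(states) <- 2L * m; length(lens) <- 2L * m }
    states[m] <- s; lens[m] <- len
    total <- total + len
    s <- sample.int(k, 1, prob = P[s, ])
  }
  states <- states[seq_len(m)]; lens <- lens[seq_len(m)]
  list(states = states, lengths = lens,
       labels = rep.int(states, lens))
}

#' Simulate one subject's microstate-structured EEG
#'
#' The state sequence is semi-Markov: states follow the zero-diagonal jump
#' matrix `transition_matrix`, with gamma-distributed dwell durations. The
#' signal within a segment is the state's template scaled by a rectified
#' sinusoid (random phase per segment); spatially correlated Gaussian noise
#' is added at `snr_db` (GFP-power ratio), and the sum is band-limited to
#' 1-30 Hz and average-referenced. Identical parameters and seed give
#' bit-identical output.
#'
#' @param params an [eeg_sim_params()].
#' @param templates 4 x channels unit-GFP template matrix (default
#'   [make_canonical_templates()] on `params$n_channels`).
#' @param transition_matrix zero-diagonal row-stochastic jump matrix
#'   (default uniform off-diagonal).
#' @return list with `recording` (an [eeg_recording()]) and `truth`
#'   (templates, transition matrix, per-sample labels, segments, params).
#' @export
simulate_eeg_subject <- function(params, templates = NULL,
                                 transition_matrix = NULL) {
  stopifnot(inherits(params, "eeg_sim_params"))
  k <- params$n_states
  if (is.null(templates)) templates <- make_canonical_templates(params$n_channels)
  positions <- attr(templates, "positions")
  templates <- unit_gfp(templates)
  if (is.null(transition_matrix)) {
    transition_matrix <- matrix(1 / (k - 1), k, k); diag(transition_matrix) <- 0
  }
  P <- check_jump_matrix(transition_matrix, k)
  if (!is.null(params$seed)) set.seed(params$seed)
  n <- as.integer(round(params$duration_s * params$fs))
  sm <- draw_semi_markov(n, params$fs, P, params$mean_duration_ms,
                         params$duration_shape)
  C <- params$n_channels
  sig <- matrix(0, C, n)
  pos0 <- 0L
  for (i in seq_along(sm$states)) {
    len <- sm$lengths[i]
    tt <- (pos0 + seq_len(len)) / params$fs
    env <- abs(sin(2 * pi * params$gfp_carrier_hz * tt + stats::runif(1, 0, 2 * pi)))
    sig[, pos0 + seq_len(len)] <- outer(templates[sm$states[i], ], env)
    pos0 <- pos0 + len
  }
  # spatially correlated noise (white channel noise mixed through a
  # distance kernel so GFP peaks stay nondegenerate), band-limited to
  # 1-30 Hz before the SNR scaling so snr_db is the in-band power ratio.
  # The template signal is narrowband by construction (rectified 10 Hz
  # carrier) and is not re-filtered: a post-hoc filter would smear the
  # instantaneous topography switches that define the microstate model.
  if (is.null(positions)) positions <- disk_layout(C)
  D2 <- as.matrix(stats::dist(positions))^2
  K <- exp(-D2 / (2 * 0.3^2))
  noise <- K %*% matrix(stats::rnorm(C * n), C, n)
  noise <- bandpass_matrix(noise, params$fs, c(1, 30))
  gfp2 <- function(m) mean(colMeans(sweep(m, 2, colMeans(m))^2))
  scale <- sqrt(gfp2(sig) / (gfp2(noise) * 10^(params$snr_db / 10)))
  x <- sig + scale * noise
  x <- sweep(x, 2, colMeans(x))
  rec <- eeg_recording(x, fs = params$fs, positions = positions)
  truth <- list(templates = templates, transition_matrix = P,
                labels = sm$labels,
                segments = data.frame(state = sm$states,
                                      length = sm$lengths),
                params = params)
  list(recording = rec, truth = truth)
}

#' Temporal metrics straight from a ground-truth label sequence
#'
#' Coverage, occurrence, mean duration and the segment-level transition
#' matrix computed directly from a state label vector, used to score
#' recovery of the generator's truth.
#'
#' @param labels integer state labels per sample.
#' @param fs sampling rate (Hz).
#' @param k number of states (default `max(labels)`).
#' @return list with `per_state` data.frame and `transition` matrix.
#' @export
metrics_from_labels <- function(labels, fs, k = max(labels)) {
  r <- rle(labels)
  n <- length(labels); T_s <- n / fs
  cov <- tabulate(labels, k) / n
  nseg <- tabulate(r$values, k)
  occ <- nseg / T_s
  dur <- vapply(seq_len(k), function(s) {
    L <- r$lengths[r$values == s]
    if (length(L)) mean(L) / fs * 1000 else NA_real_
  }, 0)
  tm <- matrix(0, k, k)
  if (length(r$values) > 1L) {
    tab <- table(factor(r$values[-length(r$values)], levels = 1:k),
                 factor(r$values[-1], levels = 1:k))
    tm[] <- as.numeric(tab)
  }
  rs <- rowSums(tm)
  tm <- tm / ifelse(rs > 0, rs, 1)
  list(per_state = data.frame(state = seq_len(k), coverage = cov,
                              occurrence = occ, duration_ms = dur,
                              n_segments = nseg),
       transition = tm)
}
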