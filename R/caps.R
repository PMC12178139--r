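# fMRI coactivation-pattern (CAP) pipeline on ROI time series: z-scoring,
# cosine k-means over individual frames, frame assignment, Wilcoxon z-maps
# with network naming, and temporal metrics.

#' Z-score each ROI within a run
#'
#' Each ROI column is standardised to mean 0, SD 1 (population SD) within
#' the subject x timepoint run.
#'
#' @param table a [roi_timeseries()].
#' @return The z-scored [roi_timeseries()].
#' @export
zscore_roi <- function(table) {
  stopifnot(inherits(table, "roi_timeseries"))
  x <- table$data
  mu <- colMeans(x)
  sdp <- sqrt(colMeans(sweep(x, 2, mu)^2))
  zero <- sdp == 0
  if (any(zero))
    ns_stop("neurostate_error_zero_variance",
            "zero-variance ROI(s): %s", paste(table$roi_ids[zero], collapse = ", "))
  table$data <- sweep(sweep(x, 2, mu), 2, sdp, "/")
  table
}

#' Sliding-window functional connectivity (diagnostic)
#'
#' Pearson correlation matrices over sliding windows of the ROI time
#' series.
#'
#' @param table a [roi_timeseries()].
#' @param window window length in frames (>= 3, <= frames).
#' @param step step between window starts (frames).
#' @return list of class `windowed_fc`: `matrices` (list of ROI x ROI
#'   correlation matrices), `window`, `step`, `starts`.
#' @export
sliding_window_fc <- function(table, window = 20, step = 1) {
  stopifnot(inherits(table, "roi_timeseries"))
  nf <- nrow(table$data)
  if (window < 3)
    ns_stop("neurostate_error_window", "window must be >= 3 frames")
  if (window > nf)
    ns_stop("neurostate_error_window", "window (%d) exceeds frames (%d)", window, nf)
  starts <- seq(1L, nf - window + 1L, by = step)
  mats <- lapply(starts, function(s)
    stats::cor(table$data[s:(s + window - 1L), , drop = FALSE]))
  structure(list(matrices = mats, window = window, step = step,
                 starts = starts),
            class = "windowed_fc")
}

unit_norm_rows <- function(m) {
  nr <- sqrt(rowSums(m^2))
  if (any(nr == 0))
    ns_stop("neurostate_error_zero_frame", "all-zero frame cannot be normalised")
  m / nr
}

#' Cosine k-means over individual BOLD frames
#'
#' Classical CAP clustering: frames (rows, z-scored) are unit-normalised
#' and clustered with distance 1 - cos(x, c); each centroid is the
#' unit-normalised mean of its assigned (unit-normalised) frames. The best
#' of `n_restarts` random initialisations by total within-cluster distance
#' is returned; ties in assignment go to the lower cluster index.
#'
#' @param frames matrix of stacked frames (rows) x ROIs, z-scored.
#' @param k number of CAPs (default 14).
#' @param n_restarts random restarts (default 50; 1000 reproduces the
#'   reference protocol).
#' @param seed optional RNG seed.
#' @param max_iter iteration cap per restart.
#' @return list of class `cap_set`: `centroids` (k x ROIs, unit norm),
#'   `k`, `objective`, `assignment`, `restart_objective`.
#' @export
cap_cluster <- function(frames, k = 14, n_restarts = 50, seed = NULL,
                        max_iter = 100) {
  frames <- as.matrix(frames)
  n <- nrow(frames)
  if (k > n)
    ns_stop("neurostate_error_k_too_large", "k = %d exceeds %d frames", k, n)
  U <- unit_norm_rows(frames)
  if (!is.null(seed)) set.seed(seed)
  best <- NULL; robj <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    Cc <- U[sample.int(n, k), , drop = FALSE]
    assign_prev <- integer(0)
    for (iter in seq_len(max_iter)) {
      S <- U %*% t(Cc)                       # cosine similarities
      assign <- max.col(S, ties.method = "first")
      for (j in which(tabulate(assign, k) == 0L)) {
        w <- which.min(S[cbind(seq_len(n), assign)])
        Cc[j, ] <- U[w, ]; assign[w] <- j
        S <- U %*% t(Cc)
        assign <- max.col(S, ties.method = "first")
      }
      if (identical(assign, assign_prev)) break
      assign_prev <- assign
      for (j in seq_len(k)) {
        m <- colMeans(U[assign == j, , drop = FALSE])
        Cc[j, ] <- m / sqrt(sum(m^2))
      }
    }
    S <- U %*% t(Cc)
    assign <- max.col(S, ties.method = "first")
    obj <- sum(1 - S[cbind(seq_len(n), assign)])
    robj[r] <- obj
    if (is.null(best) || obj < best$objective)
      best <- list(centroids = Cc, assignment = assign, objective = obj)
  }
  structure(list(centroids = best$centroids, k = k,
                 objective = best$objective, assignment = best$assignment,
                 restart_objective = robj),
            class = "cap_set")
}

#' @export
print.cap_set <- function(x, ...) {
  cat(sprintf("<cap_set> k = %d, within-cluster distance %.4f\n",
              x$k, x$objective))
  if (!is.null(x$names)) cat("  ", paste(x$names, collapse = ", "), "\n")
  invisible(x)
}

#' Assign frames to their nearest CAP by cosine similarity
#'
#' @param table a z-scored [roi_timeseries()] or a plain frames x ROIs
#'   matrix (ROI order must match the centroids).
#' @param cap_set a `cap_set` from [cap_cluster()].
#' @return integer vector of per-frame CAP indices (ties go to the lower
#'   index).
#' @export
assign_frames <- function(table, cap_set) {
  x <- if (inherits(table, "roi_timeseries")) table$data else as.matrix(table)
  if (ncol(x) != ncol(cap_set$centroids))
    ns_stop("neurostate_error_roi_mismatch",
            "table has %d ROIs, centroids %d", ncol(x), ncol(cap_set$centroids))
  S <- unit_norm_rows(x) %*% t(cap_set$centroids)
  max.col(S, ties.method = "first")
}

#' Per-subject CAP maps ("averaged volumes")
#'
#' Mean of the subject's z-scored frames assigned to each CAP.
#'
#' @param frames z-scored frames x ROIs matrix for one subject.
#' @param labels per-frame CAP indices.
#' @param k number of CAPs.
#' @return k x ROIs matrix (NA rows for CAPs the subject never visits).
#' @export
subject_cap_maps <- function(frames, labels, k) {
  out <- matrix(NA_real_, k, ncol(frames))
  for (j in seq_len(k)) {
    idx <- which(labels == j)
    if (length(idx)) out[j, ] <- colMeans(frames[idx, , drop = FALSE])
  }
  out
}

#' CAP z-maps, Wilcoxon significance and network naming
#'
#' For each CAP: the ROI-wise mean of its assigned z-scored frames (the
#' "z-score" map), a Wilcoxon signed-rank test of those frame values
#' against zero median per ROI (Bonferroni-corrected across ROIs within the
#' CAP), the network-level mean z given the atlas, and the name
#' `"<argmax network>+ <argmin network>-"`. CAPs with fewer than
#' `min_frames` assigned frames are flagged and not tested.
#'
#' @param frames stacked z-scored frames x ROIs matrix.
#' @param labels per-frame CAP indices (from [assign_frames()]).
#' @param atlas atlas map (roi_id -> network) covering the frame columns.
#' @param alpha significance level after Bonferroni correction.
#' @param k number of CAPs (default `max(labels)`).
#' @param min_frames minimum assigned frames required for testing.
#' @return list of class `cap_zmaps`: `z` (k x ROIs), `p_bonferroni`,
#'   `significant` (logical k x ROIs), `network_z` (k x 7), `names`,
#'   `n_frames`, `tested`.
#' @export
cap_zscores <- function(frames, labels, atlas, alpha = 0.05,
                        k = max(labels), min_frames = 5L) {
  frames <- as.matrix(frames)
  nets <- as.character(atlas)
  if (length(nets) != ncol(frames))
    ns_stop("neurostate_error_roi_mismatch", "atlas does not cover the frame columns")
  nr <- ncol(frames)
  z <- p <- matrix(NA_real_, k, nr)
  net_z <- matrix(NA_real_, k, length(YEO7), dimnames = list(NULL, YEO7))
  names_out <- rep(NA_character_, k)
  n_frames <- tabulate(labels, k)
  tested <- n_frames >= min_frames
  for (j in seq_len(k)) {
    if (!tested[j]) next
    fj <- frames[labels == j, , drop = FALSE]
    z[j, ] <- colMeans(fj)
    p[j, ] <- pmin(1, vapply(seq_len(nr), function(r) {
      v <- fj[, r]
      if (all(v == 0)) return(1)
      suppressWarnings(stats::wilcox.test(v, mu = 0)$p.value)
    }, 0) * nr)
    for (nw in YEO7) net_z[j, nw] <- mean(z[j, nets == nw])
    names_out[j] <- paste0(YEO7[which.max(net_z[j, ])], "+ ",
                           YEO7[which.min(net_z[j, ])], "-")
  }
  structure(list(z = z, p_bonferroni = p, significant = p < alpha,
                 network_z = net_z, names = names_out,
                 n_frames = n_frames, tested = tested),
            class = "cap_zmaps")
}

#' Temporal CAP metrics from a state sequence
#'
#' Fractional occupancy (share of frames), dwell time (mean consecutive run
#' length times TR, seconds; 0 when the state is absent, with
#' `present = FALSE`), and appearance rate (distinct entries per minute).
#'
#' @param labels per-frame CAP indices (integer vector).
#' @param tr repetition time in seconds.
#' @param k number of CAPs (default `max(labels)`).
#' @return data.frame with one row per CAP: `state`,
#'   `fractional_occupancy`, `dwell_time_s`, `appearance_rate_per_min`,
#'   `n_visits`, `present`.
#' @export
cap_temporal_metrics <- function(labels, tr, k = max(labels)) {
  if (!length(labels))
    ns_stop("neurostate_error_empty", "empty CAP state sequence")
  if (tr <= 0) ns_stop("neurostate_error_bad_tr", "tr must be > 0")
  nf <- length(labels)
  r <- rle(labels)
  fo <- tabulate(labels, k) / nf
  visits <- tabulate(r$values, k)
  dwell <- vapply(seq_len(k), function(s) {
    L <- r$lengths[r$values == s]
    if (length(L)) mean(L) * tr else 0
  }, 0)
  rate <- visits / (nf * tr / 60)
  data.frame(state = seq_len(k), fractional_occupancy = fo,
             dwell_time_s = dwell, appearance_rate_per_min = rate,
             n_visits = visits, present = visits > 0L)
}
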