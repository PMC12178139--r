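# EEG microstate pipeline: band-pass/resample, global field power, GFP-peak
# topographies, polarity-invariant modified k-means with restarts,
# cross-validation based choice of k, group templates, canonical sorting,
# back-fitting with minimum-duration smoothing, and temporal metrics.

#' Band-pass filter, resample and average-reference an EEG recording
#'
#' Zero-phase FIR band-pass (Hamming-windowed, applied forward and backward
#' via FFT convolution), optional resampling to `target_fs`, then common
#' average reference.
#'
#' @param rec an [eeg_recording()].
#' @param band numeric length-2, pass band in Hz (default 1-30).
#' @param target_fs output sampling rate in Hz (default 500).
#' @return A filtered, average-referenced [eeg_recording()] at `target_fs`.
#' @export
preprocess_eeg <- function(rec, band = c(1, 30), target_fs = 500) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (fs < 2 * band[2])
    ns_stop("neurostate_error_nyquist",
            "sampling rate %g Hz is below the Nyquist rate for a %g Hz band edge",
            fs, band[2])
  x <- bandpass_matrix(rec$data, fs, band)
  if (abs(fs - target_fs) > 1e-9) {
    fr <- as.integer(gmp_ratio(target_fs, fs))
    x <- t(apply(x, 1, function(ch) signal::resample(ch, fr[1], fr[2])))
    fs <- target_fs
  }
  x <- sweep(x, 2, colMeans(x))      # common average reference
  eeg_recording(x, fs = fs, channel_names = rec$channel_names,
                positions = rec$positions, subject_id = rec$subject_id,
                timepoint = rec$timepoint)
}

# small rational approximation p/q of a/b for resample()
gmp_ratio <- function(a, b) {
  scale <- 1e6
  p <- round(a * scale); q <- round(b * scale)
  g <- gcd2(p, q)
  c(p / g, q / g)
}
gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

# zero-phase FIR band-pass on a channels x samples matrix
bandpass_matrix <- function(x, fs, band = c(1, 30), order = NULL) {
  if (is.null(order)) {
    order <- min(round(fs), ncol(x) - 1L)
    if (order %% 2L == 1L) order <- order - 1L
  }
  b <- signal::fir1(order, band / (fs / 2), type = "pass")
  half <- order / 2
  one_pass <- function(ch) {
    y <- signal::fftfilt(b, c(ch, numeric(order)))
    y[(half + 1):(half + length(ch))]          # compensate group delay
  }
  t(apply(x, 1, function(ch) rev(one_pass(rev(one_pass(ch))))))
}

#' Global field power
#'
#' GFP(t) is the population standard deviation of the instantaneous scalp
#' map across channels (square root of the mean squared deviation from the
#' channel mean). The recording is average-referenced internally.
#'
#' @param rec an [eeg_recording()] with >= 2 channels.
#' @return list with `values` (non-negative, one per sample) and `fs`,
#'   class `gfp_series`.
#' @export
compute_gfp <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$data) < 2L)
    ns_stop("neurostate_error_too_few_channels", "GFP needs >= 2 channels")
  v <- sweep(rec$data, 2, colMeans(rec$data))
  structure(list(values = sqrt(colMeans(v^2)), fs = rec$fs),
            class = "gfp_series")
}

#' Indices of local GFP maxima
#'
#' Strictly-greater-than-both-neighbours local maxima; series endpoints are
#' never peaks.
#'
#' @param gfp a `gfp_series` from [compute_gfp()] or a numeric vector.
#' @return integer vector of peak sample indices (possibly empty).
#' @export
extract_gfp_peaks <- function(gfp) {
  v <- if (inherits(gfp, "gfp_series")) gfp$values else gfp
  n <- length(v)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  i[v[i] > v[i - 1L] & v[i] > v[i + 1L]]
}

# rows centered and L2-normalised; zero rows left at zero
unit_rows <- function(m) {
  m <- sweep(m, 1, rowMeans(m))
  nr <- sqrt(rowSums(m^2))
  nr[nr == 0] <- 1
  m / nr
}

new_template_set <- function(maps, labels = NULL, gev_total = NA_real_,
                             provenance = "individual") {
  maps <- matrix(as.numeric(maps), nrow(maps), ncol(maps))
  k <- nrow(maps)
  if (is.null(labels)) labels <- paste0("M", seq_len(k))
  rownames(maps) <- labels
  structure(list(maps = maps, labels = labels, k = k,
                 gev_total = gev_total, provenance = provenance),
            class = "microstate_templates")
}

#' @export
print.microstate_templates <- function(x, ...) {
  cat(sprintf("<microstate_templates> k = %d (%s), labels %s, GEV = %s\n",
              x$k, x$provenance, paste(x$labels, collapse = ","),
              format(x$gev_total, digits = 4)))
  invisible(x)
}

#' Polarity-invariant modified k-means for topographic maps
#'
#' Clusters scalp maps ignoring polarity: each map is assigned to the
#' template maximising the squared spatial (Pearson) correlation, and each
#' template is updated to the dominant eigenvector of its assigned maps'
#' channel cross-product matrix. The objective is the global explained
#' variance, GEV = sum_i w_i corr_i^2 / sum_i w_i with weights w_i = GFP_i^2
#' of the input maps; the best of `n_restarts` random initialisations is
#' returned.
#'
#' @param maps n x channels matrix of topographies (average-referenced
#'   internally).
#' @param k number of clusters (<= n).
#' @param n_restarts random restarts (default 50).
#' @param seed optional RNG seed for reproducible restarts.
#' @param update `"eigen"` (dominant-eigenvector update, default) or
#'   `"mean"` (polarity-aligned mean).
#' @param max_iter,tol convergence controls: stop when the relative GEV
#'   change falls below `tol` or after `max_iter` iterations.
#' @return A `microstate_templates` object; attribute `assignment` holds the
#'   winning restart's per-map cluster indices, `restart_gev` the GEV of
#'   every restart.
#' @export
modified_kmeans <- function(maps, k, n_restarts = 50, seed = NULL,
                            update = c("eigen", "mean"),
                            max_iter = 200, tol = 1e-7) {
  update <- match.arg(update)
  maps <- as.matrix(maps)
  n <- nrow(maps); C <- ncol(maps)
  if (k > n)
    ns_stop("neurostate_error_k_too_large", "k = %d exceeds %d maps", k, n)
  X <- sweep(maps, 1, rowMeans(maps))          # centered raw maps
  g2 <- rowSums(X^2)                           # proportional to GFP^2
  if (all(g2 == 0))
    ns_stop("neurostate_error_degenerate_map", "all maps are constant")
  U <- X / sqrt(pmax(g2, .Machine$double.eps)) # unit-L2 rows
  if (!is.null(seed)) set.seed(seed)
  best <- NULL; restart_gev <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    Tau <- U[sample.int(n, k), , drop = FALSE]
    gev_prev <- -Inf; assign <- NULL; corr2 <- NULL
    for (iter in seq_len(max_iter)) {
      R <- U %*% t(Tau)                        # n x k correlations
      assign <- max.col(R^2, ties.method = "first")
      corr2 <- R[cbind(seq_len(n), assign)]^2
      # empty clusters: reseed from the worst-explained map
      for (j in which(tabulate(assign, k) == 0L)) {
        w <- which.max(g2 * (1 - corr2))
        Tau[j, ] <- U[w, ]
        assign[w] <- j
        corr2[w] <- 1
      }
      for (j in seq_len(k)) {
        idx <- which(assign == j)
        if (update == "eigen") {
          S <- crossprod(X[idx, , drop = FALSE])
          v <- eigen(S, symmetric = TRUE)$vectors[, 1]
        } else {
          sgn <- sign(U[idx, , drop = FALSE] %*% Tau[j, ])
          sgn[sgn == 0] <- 1
          v <- colSums(X[idx, , drop = FALSE] * as.vector(sgn))
        }
        v <- v - mean(v)
        Tau[j, ] <- v / sqrt(sum(v^2))
      }
      R <- U %*% t(Tau)
      assign <- max.col(R^2, ties.method = "first")
      corr2 <- R[cbind(seq_len(n), assign)]^2
      gev <- sum(g2 * corr2) / sum(g2)
      if (is.finite(gev_prev) && gev - gev_prev <= tol * max(gev_prev, 1e-12))
        break
      gev_prev <- gev
    }
    gev <- sum(g2 * corr2) / sum(g2)
    restart_gev[r] <- gev
    if (is.null(best) || gev > best$gev)
      best <- list(Tau = Tau, assign = assign, gev = gev)
  }
  maps_out <- best$Tau * sqrt(C)               # unit-L2 -> unit-GFP
  out <- new_template_set(maps_out, gev_total = best$gev)
  attr(out, "assignment") <- best$assign
  attr(out, "restart_gev") <- restart_gev
  out
}

#' Choose the number of microstate classes by the cross-validation criterion
#'
#' Fits [modified_kmeans()] for each k and evaluates the predictive-residual
#' cross-validation criterion CV(k) = sigma2_k * ((C-1)/(C-1-k))^2, where C
#' is the channel count and sigma2_k the mean residual variance of the maps
#' about their (polarity-aligned) assigned templates. Returns the argmin.
#'
#' @inheritParams modified_kmeans
#' @param k_range candidate k values (default 2:8); the maximum must be
#'   below both n and C-1.
#' @return list with `k_star`, `criterion` (named per k) and `fits` (the
#'   fitted template sets).
#' @export
select_k_cv <- function(maps, k_range = 2:8, n_restarts = 50, seed = NULL) {
  maps <- as.matrix(maps)
  n <- nrow(maps); C <- ncol(maps)
  if (max(k_range) >= min(n, C - 1))
    ns_stop("neurostate_error_k_range",
            "max(k_range) must be < n maps and < channels - 1")
  X <- sweep(maps, 1, rowMeans(maps))
  cv <- numeric(length(k_range)); fits <- vector("list", length(k_range))
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    fit <- modified_kmeans(maps, k, n_restarts = n_restarts, seed = seeds[i])
    Tau <- unit_rows(fit$maps)
    assign <- attr(fit, "assignment")
    proj <- rowSums(X * Tau[assign, , drop = FALSE])
    sigma2 <- sum(rowSums(X^2) - proj^2) / (n * (C - 1))
    cv[i] <- sigma2 * ((C - 1) / (C - 1 - k))^2
    fits[[i]] <- fit
  }
  names(cv) <- k_range
  list(k_star = k_range[which.min(cv)], criterion = cv, fits = fits)
}

#' Second-level clustering of individual template sets into group templates
#'
#' Concatenates the (unit-GFP, polarity-free) individual maps and reruns
#' [modified_kmeans()] to obtain one group template set.
#'
#' @param sets list of `microstate_templates` sharing a channel space.
#' @param k number of group classes (default 4).
#' @inheritParams modified_kmeans
#' @return A `microstate_templates` with provenance `"group"`.
#' @export
build_group_templates <- function(sets, k = 4, n_restarts = 50, seed = NULL) {
  ncs <- vapply(sets, function(s) ncol(s$maps), 0L)
  if (length(unique(ncs)) != 1L)
    ns_stop("neurostate_error_channel_mismatch",
            "individual template sets have mixed channel counts")
  stacked <- do.call(rbind, lapply(sets, function(s) s$maps))
  fit <- modified_kmeans(stacked, k, n_restarts = n_restarts, seed = seed)
  fit$provenance <- "group"
  fit
}

perms <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- perms(k - 1L)
  out <- matrix(0L, 0, k)
  for (i in seq_len(k)) {
    rest <- seq_len(k)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  out
}

#' Sort a template set against a reference
#'
#' Finds the permutation of the set's maps maximising the total absolute
#' spatial correlation to the reference maps (exhaustive over k! for
#' k <= 6), flips signs so every correlation to the reference is positive,
#' and adopts the reference labels. Ties are broken by the lexicographically
#' smallest permutation.
#'
#' @param set,reference `microstate_templates` with equal k and channels.
#' @param allow_large set `TRUE` to permit k > 6 (k! permutations).
#' @return The sorted `microstate_templates`; attribute `match_corr` holds
#'   the per-class correlation to the reference.
#' @export
sort_templates <- function(set, reference, allow_large = FALSE) {
  if (set$k != reference$k)
    ns_stop("neurostate_error_k_mismatch", "template sets differ in k")
  if (ncol(set$maps) != ncol(reference$maps))
    ns_stop("neurostate_error_channel_mismatch", "channel spaces differ")
  if (set$k > 6 && !allow_large)
    ns_stop("neurostate_error_k_guard",
            "exhaustive sorting guarded for k > 6; pass allow_large = TRUE")
  A <- unit_rows(set$maps); B <- unit_rows(reference$maps)
  Rm <- A %*% t(B)                         # corr(set i, ref j)
  P <- perms(set$k)
  scores <- apply(P, 1, function(p) sum(abs(Rm[cbind(p, seq_len(set$k))])))
  best <- which(scores >= max(scores) - 1e-12)[1]  # perms are in lexicographic order
  p <- P[best, ]
  maps <- set$maps[p, , drop = FALSE]
  mc <- Rm[cbind(p, seq_len(set$k))]
  flip <- ifelse(mc < 0, -1, 1)
  maps <- maps * flip
  out <- new_template_set(maps, labels = reference$labels,
                          gev_total = set$gev_total,
                          provenance = set$provenance)
  attr(out, "match_corr") <- abs(mc)
  out
}

#' Canonical A-D reference templates on a montage
#'
#' Classical microstate taxonomy maps (see [make_canonical_templates()])
#' evaluated on the recording's channel layout, for use as the sorting
#' reference.
#'
#' @param rec an [eeg_recording()] (its `positions` are used when present).
#' @return A `microstate_templates` labelled A-D.
#' @export
canonical_reference <- function(rec) {
  pos <- rec$positions
  maps <- if (is.null(pos)) make_canonical_templates(nrow(rec$data))
          else make_canonical_templates(positions = pos)
  new_template_set(unclass(maps)[, , drop = FALSE],
                   labels = c("A", "B", "C", "D"), provenance = "canonical")
}

segments_from_labels <- function(labels) {
  r <- rle(labels)
  start <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  data.frame(state = r$values, start = start, length = r$lengths)
}

#' Back-fit templates to a recording and smooth the label sequence
#'
#' Labels every sample with the template of maximal absolute spatial
#' correlation, then repeatedly relabels the shortest segment below the
#' minimum duration (ties: earliest) to the adjacent segment whose template
#' correlates better with the short segment's samples, until every segment
#' is at least `min_duration_ms` long. Boundary segments merge inward.
#'
#' @param rec an [eeg_recording()] sharing the templates' channel space.
#' @param templates a `microstate_templates`.
#' @param min_duration_ms minimum segment duration (default 30 ms; 0
#'   disables smoothing).
#' @param gfp_floor_quantile optional GFP quantile in `[0,1)`; samples with
#'   GFP below it are left unlabeled (state 0) and act as segment walls.
#' @return A `microstate_segmentation`: per-sample `labels` (0 =
#'   unlabeled), `segments` (state/start/length over labeled runs), per-
#'   sample `corr` (absolute correlation to the winning template), `fs`,
#'   `k`, and the template `labels` vector.
#' @export
backfit <- function(rec, templates, min_duration_ms = 30,
                    gfp_floor_quantile = 0) {
  stopifnot(inherits(rec, "eeg_recording"),
            inherits(templates, "microstate_templates"))
  if (ncol(templates$maps) != nrow(rec$data))
    ns_stop("neurostate_error_channel_mismatch",
            "recording and templates differ in channel count")
  n <- ncol(rec$data)
  if (n == 0L) ns_stop("neurostate_error_empty", "empty recording")
  V <- sweep(rec$data, 2, colMeans(rec$data))
  nv <- sqrt(colSums(V^2)); nv[nv == 0] <- 1
  Tau <- unit_rows(templates$maps)
  AC <- abs(Tau %*% (V / rep(nv, each = nrow(V))))   # k x n |corr|
  labels <- max.col(t(AC), ties.method = "first")
  excluded <- rep(FALSE, n)
  if (gfp_floor_quantile > 0) {
    gfp <- sqrt(colMeans(V^2))
    excluded <- gfp < stats::quantile(gfp, gfp_floor_quantile)
    labels[excluded] <- 0L
  }
  min_len <- round(min_duration_ms * rec$fs / 1000)
  seg <- segments_from_labels(labels)
  if (min_len > 1L) {
    repeat {
      lab_idx <- which(seg$state > 0L & seg$length < min_len)
      if (!length(lab_idx)) break
      i <- lab_idx[which.min(seg$length[lab_idx])]
      span <- seg$start[i]:(seg$start[i] + seg$length[i] - 1L)
      left  <- if (i > 1L && seg$state[i - 1L] > 0L) seg$state[i - 1L] else NA
      right <- if (i < nrow(seg) && seg$state[i + 1L] > 0L) seg$state[i + 1L] else NA
      if (is.na(left) && is.na(right)) {
        # isolated between walls (or the whole recording): freeze as is
        seg$state[i] <- -seg$state[i]
      } else {
        target <- if (is.na(right)) left
                  else if (is.na(left)) right
                  else if (mean(AC[left, span]) >= mean(AC[right, span])) left
                  else right
        seg$state[i] <- target
      }
      labels2 <- rep.int(seg$state, seg$length)
      seg <- segments_from_labels(labels2)
    }
    labels <- rep.int(abs(seg$state), seg$length)
    seg <- segments_from_labels(labels)
  }
  corr <- ifelse(labels > 0L, AC[cbind(pmax(labels, 1L), seq_len(n))], NA_real_)
  structure(list(labels = labels,
                 segments = seg[seg$state > 0L, , drop = FALSE],
                 corr = corr, fs = rec$fs, k = templates$k,
                 state_labels = templates$labels),
            class = "microstate_segmentation")
}

#' Temporal microstate metrics from a segmentation
#'
#' Per state: coverage (share of labeled samples), occurrence (segments per
#' second of labeled time), mean duration (ms), GEV restricted to the
#' state's samples, and the segment-level transition matrix
#' P(s -> s') = count(s followed by s') / count(s followed by anything),
#' zero diagonal. With `per_sample_transitions = TRUE` the matrix instead
#' counts all consecutive sample pairs (self-transitions included).
#'
#' @param seg a `microstate_segmentation`.
#' @param gfp the matching `gfp_series` (same recording).
#' @param per_sample_transitions count per-sample transitions including
#'   self-transitions instead of segment-level changes.
#' @return list of class `microstate_metrics`: `per_state` data.frame
#'   (state, coverage, occurrence, duration_ms, gev, n_segments),
#'   `transition` k x k matrix, `gev_total`.
#' @export
compute_microstate_metrics <- function(seg, gfp,
                                       per_sample_transitions = FALSE) {
  stopifnot(inherits(seg, "microstate_segmentation"))
  gv <- if (inherits(gfp, "gfp_series")) gfp$values else gfp
  lab <- seg$labels
  keep <- lab > 0L
  if (!any(keep))
    ns_stop("neurostate_error_no_labels", "segmentation has no labeled samples")
  k <- seg$k
  n_lab <- sum(keep)
  T_lab <- n_lab / seg$fs
  segs <- seg$segments
  cov <- tabulate(lab[keep], k) / n_lab
  nseg <- tabulate(segs$state, k)
  occ <- nseg / T_lab
  dur <- vapply(seq_len(k), function(s) {
    L <- segs$length[segs$state == s]
    if (length(L)) mean(L) / seg$fs * 1000 else NA_real_
  }, 0)
  denom <- sum(gv[keep]^2)
  gev <- vapply(seq_len(k), function(s) {
    i <- which(keep & lab == s)
    sum(gv[i]^2 * seg$corr[i]^2) / denom
  }, 0)
  if (per_sample_transitions) {
    a <- lab[-length(lab)]; b <- lab[-1]
    ok <- a > 0L & b > 0L
    tm <- matrix(0, k, k)
    tab <- table(factor(a[ok], levels = 1:k), factor(b[ok], levels = 1:k))
    tm[] <- as.numeric(tab)
  } else {
    ss <- segs$state
    tm <- matrix(0, k, k)
    if (length(ss) > 1L) {
      tab <- table(factor(ss[-length(ss)], levels = 1:k),
                   factor(ss[-1], levels = 1:k))
      tm[] <- as.numeric(tab)
    }
  }
  rs <- rowSums(tm)
  tm <- tm / ifelse(rs > 0, rs, 1)
  state_names <- seg$state_labels %||% paste0("M", 1:k)
  dimnames(tm) <- list(from = state_names, to = state_names)
  structure(list(
    per_state = data.frame(state = state_names, coverage = cov,
                           occurrence = occ, duration_ms = dur,
                           gev = gev, n_segments = nseg),
    transition = tm,
    gev_total = sum(gev)),
    class = "microstate_metrics")
}
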