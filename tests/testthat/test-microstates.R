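# Microstate pipeline: filtering, GFP, peak extraction, modified k-means
# with its brute-force oracle, k selection, sorting, back-fitting and
# temporal metrics.

test_that("band-pass removes out-of-band sinusoids and rejects sub-Nyquist rates", {
  fs <- 500
  t <- seq_len(fs * 4) / fs
  x50 <- rbind(sin(2 * pi * 50 * t), cos(2 * pi * 50 * t),
               sin(2 * pi * 50 * t + 1), cos(2 * pi * 50 * t + 2),
               sin(2 * pi * 50 * t + 3), cos(2 * pi * 50 * t + 4),
               sin(2 * pi * 50 * t + 5), cos(2 * pi * 50 * t + 6))
  rec <- eeg_recording(x50, fs = fs)
  out <- preprocess_eeg(rec)
  core <- (fs + 1):(3 * fs)    # avoid filter edge transients
  expect_lt(sqrt(mean(out$data[, core]^2)) / sqrt(mean(x50[, core]^2)), 0.01)

  expect_error(preprocess_eeg(eeg_recording(x50, fs = 40)),
               class = "neurostate_error_nyquist")
})

test_that("in-band content passes through nearly unchanged", {
  fs <- 500
  t <- seq_len(fs * 4) / fs
  x <- rbind(sin(2 * pi * 10 * t), cos(2 * pi * 10 * t),
             sin(2 * pi * 15 * t), cos(2 * pi * 5 * t),
             sin(2 * pi * 12 * t), cos(2 * pi * 8 * t),
             sin(2 * pi * 20 * t), cos(2 * pi * 18 * t))
  rec <- eeg_recording(x, fs = fs)
  out <- preprocess_eeg(rec)
  ref <- sweep(x, 2, colMeans(x))     # average-referenced input
  core <- (fs + 1):(3 * fs)
  err <- sqrt(mean((out$data[, core] - ref[, core])^2)) /
    sqrt(mean(ref[, core]^2))
  expect_lt(err, 0.02)
})

test_that("GFP matches its population-SD definition", {
  rec <- eeg_recording(matrix(5, 4, 3), fs = 100)
  expect_equal(compute_gfp(rec)$values, rep(0, 3))
  rec2 <- eeg_recording(matrix(c(1, -1), 2, 1), fs = 100)
  expect_equal(compute_gfp(rec2)$values, 1)
  set.seed(8)
  x <- matrix(rnorm(8 * 20), 8, 20)
  g <- compute_gfp(eeg_recording(x, fs = 100))$values
  oracle <- apply(x, 2, function(v) sqrt(mean((v - mean(v))^2)))
  expect_equal(g, oracle, tolerance = 1e-12)
  expect_error(compute_gfp(eeg_recording(matrix(1, 1, 5), fs = 1)),
               class = "neurostate_error_too_few_channels")
})

test_that("GFP peaks are strict interior local maxima", {
  expect_identical(extract_gfp_peaks(1:10), integer(0))
  expect_identical(extract_gfp_peaks(c(0, 1, 0, 1, 0)), c(2L, 4L))
  set.seed(2)
  v <- abs(sin(seq(0, 40, by = 0.07))) + 0.3 * sin(seq(0, 90, length.out = 572))
  brute <- which(vapply(2:(length(v) - 1), function(i)
    v[i] > v[i - 1] && v[i] > v[i + 1], TRUE)) + 1L
  expect_identical(extract_gfp_peaks(v), brute)
})


test_that("modified k-means recovers noiseless templates up to polarity", {
  tm <- make_canonical_templates(16)[c(1, 3), ]
  tm[2, ] <- tm[2, ] - tm[1, ] * sum(tm[1, ] * tm[2, ]) / sum(tm[1, ]^2)
  tm <- neurostate:::unit_gfp(tm)
  set.seed(4)
  maps <- tm[rep(1:2, each = 10), ] * sample(c(-1, 1), 20, replace = TRUE) *
    stats::runif(20, 0.5, 2)
  fit <- modified_kmeans(maps, 2, n_restarts = 5, seed = 1)
  expect_equal(fit$gev_total, 1, tolerance = 1e-9)
  cc <- abs(stats::cor(t(fit$maps), t(tm)))
  expect_equal(sort(unname(apply(cc, 1, max))), c(1, 1), tolerance = 1e-9)
  # k = n distinct maps explains everything
  set.seed(5)
  m6 <- matrix(rnorm(6 * 12), 6, 12)
  expect_equal(modified_kmeans(m6, 6, n_restarts = 3, seed = 1)$gev_total, 1,
               tolerance = 1e-9)
  expect_error(modified_kmeans(m6, 7), class = "neurostate_error_k_too_large")
})

test_that("modified k-means attains the exhaustive-partition optimum", {
  set.seed(9)
  for (rep in 1:3) {
    maps <- matrix(rnorm(6 * 8), 6, 8)
    fit <- modified_kmeans(maps, 2, n_restarts = 30, seed = rep)
    expect_equal(fit$gev_total, brute_force_gev2(maps), tolerance = 1e-8)
  }
})

test_that("clustering and metrics are polarity-invariant", {
  p <- eeg_sim_params(duration_s = 4, seed = 13)
  sim <- simulate_eeg_subject(p)
  rec <- sim$recording
  pk <- extract_gfp_peaks(compute_gfp(rec))
  maps <- t(rec$data[, pk])
  flip <- rep(1, nrow(maps)); flip[seq(1, nrow(maps), by = 3)] <- -1
  f1 <- modified_kmeans(maps, 4, n_restarts = 5, seed = 2)
  f2 <- modified_kmeans(maps * flip, 4, n_restarts = 5, seed = 2)
  expect_equal(f1$gev_total, f2$gev_total, tolerance = 1e-9)
  expect_identical(attr(f1, "assignment"), attr(f2, "assignment"))
  # sign-flipping a time window leaves back-fit labels unchanged
  tset <- neurostate:::new_template_set(sim$truth$templates)
  rec2 <- rec; rec2$data[, 300:900] <- -rec2$data[, 300:900]
  expect_identical(backfit(rec, tset)$labels, backfit(rec2, tset)$labels)
})

test_that("the CV criterion recovers the true cluster number on clean data", {
  tm <- neurostate:::unit_gfp(make_canonical_templates(16)[c(1, 4), ])
  set.seed(6)
  maps <- tm[rep(1:2, each = 15), ] * sample(c(-1, 1), 30, replace = TRUE)
  maps <- maps + matrix(rnorm(30 * 16, sd = 0.05), 30, 16)
  sel <- select_k_cv(maps, 2:5, n_restarts = 10, seed = 3)
  expect_identical(sel$k_star, 2L)
  one <- select_k_cv(maps, c(2, 2), n_restarts = 5, seed = 1)
  expect_identical(unname(one$k_star), 2)
  expect_error(select_k_cv(maps, 2:20), class = "neurostate_error_k_range")
})

test_that("group templates recover per-stratum truth", {
  tmA <- make_canonical_templates(24)
  sets <- lapply(1:5, function(i)
    neurostate:::new_template_set(unclass(tmA) *
                                    sample(c(-1, 1), 4, replace = TRUE)))
  grp <- build_group_templates(sets, k = 4, n_restarts = 10, seed = 2)
  srt <- sort_templates(grp, neurostate:::new_template_set(unclass(tmA),
                                                           labels = LETTERS[1:4]))
  expect_true(all(attr(srt, "match_corr") > 0.999))
  expect_equal(grp$gev_total, 1, tolerance = 1e-9)
  single <- build_group_templates(sets[1], k = 4, n_restarts = 10, seed = 2)
  s1 <- sort_templates(single, neurostate:::new_template_set(unclass(tmA)))
  expect_true(all(attr(s1, "match_corr") > 0.999))
})

test_that("template sorting finds the optimal permutation and polarity", {
  ref <- neurostate:::new_template_set(unclass(make_canonical_templates(20)),
                                       labels = LETTERS[1:4])
  # already aligned -> identity
  aligned <- sort_templates(ref, ref)
  expect_identical(aligned$maps, ref$maps)
  # known shuffle with sign flips -> inverse permutation recovered
  perm <- c(3, 1, 4, 2)
  shuffled <- neurostate:::new_template_set(ref$maps[perm, ] * c(-1, 1, -1, 1))
  back <- sort_templates(shuffled, ref)
  expect_equal(unname(back$maps), unname(ref$maps), tolerance = 1e-12)
  # random maps: agreement with an independent exhaustive assignment oracle
  set.seed(12)
  rnd <- neurostate:::new_template_set(neurostate:::unit_gfp(matrix(rnorm(80), 4, 20)))
  srt <- sort_templates(rnd, ref)
  cm <- abs(stats::cor(t(rnd$maps), t(ref$maps)))
  best <- -Inf; best_assign <- NULL
  for (a in 1:4) for (b in setdiff(1:4, a)) for (cc in setdiff(1:4, c(a, b))) {
    d <- setdiff(1:4, c(a, b, cc))
    sc <- cm[a, 1] + cm[b, 2] + cm[cc, 3] + cm[d, 4]
    if (sc > best) { best <- sc; best_assign <- c(a, b, cc, d) }
  }
  expect_equal(sum(attr(srt, "match_corr")), best, tolerance = 1e-10)
  expect_error(sort_templates(rnd, neurostate:::new_template_set(matrix(rnorm(60), 4, 15))),
               class = "neurostate_error_channel_mismatch")
})

test_that("back-fitting smooths sub-threshold segments by the stated rule", {
  tm <- make_canonical_templates(16)
  tset <- neurostate:::new_template_set(unclass(tm), labels = LETTERS[1:4])
  rec <- rec_from_templates(tm, c(1, 2, 1), c(100, 10, 100))
  seg <- backfit(rec, tset, min_duration_ms = 30)
  expect_identical(nrow(seg$segments), 1L)
  expect_identical(seg$segments$state, 1L)
  expect_identical(seg$segments$length, 105L)   # 210 ms at 500 Hz
  expect_true(all(seg$segments$length >= round(30 * 500 / 1000)))
  # pure single-template recording
  recA <- rec_from_templates(tm, 1, 2000)
  segA <- backfit(recA, tset)
  m <- compute_microstate_metrics(segA, compute_gfp(recA))
  expect_equal(m$per_state$coverage[1], 1)
  # zero threshold leaves the raw argmax labelling untouched
  raw <- backfit(rec, tset, min_duration_ms = 0)
  expect_identical(sort(unique(raw$labels)), c(1L, 2L))
})

test_that("temporal metrics match hand-computed values and identities", {
  tm <- make_canonical_templates(16)
  tset <- neurostate:::new_template_set(unclass(tm), labels = LETTERS[1:4])
  recA <- rec_from_templates(tm, 1, 2000)
  mA <- compute_microstate_metrics(backfit(recA, tset), compute_gfp(recA))
  expect_equal(mA$per_state$coverage[1], 1)
  expect_equal(mA$per_state$occurrence[1], 0.5)
  expect_equal(mA$per_state$duration_ms[1], 2000)

  alt <- rec_from_templates(tm, rep(c(1, 2), 50), rep(100, 100))
  malt <- compute_microstate_metrics(backfit(alt, tset), compute_gfp(alt))
  expect_equal(malt$per_state$coverage[1:2], c(0.5, 0.5))
  expect_equal(malt$per_state$occurrence[1:2], c(5, 5))
  expect_equal(malt$per_state$duration_ms[1:2], c(100, 100))
  expect_equal(malt$transition["A", "B"], 1)
  expect_equal(malt$transition["B", "A"], 1)

  # identities on an arbitrary segmentation
  p <- eeg_sim_params(duration_s = 8, seed = 31)
  sim <- simulate_eeg_subject(p)
  seg <- backfit(sim$recording,
                 neurostate:::new_template_set(sim$truth$templates))
  mm <- compute_microstate_metrics(seg, compute_gfp(sim$recording))
  ps <- mm$per_state
  expect_equal(sum(ps$coverage), 1, tolerance = 1e-12)
  expect_equal(ps$coverage,
               ps$occurrence * ps$duration_ms / 1000, tolerance = 1e-12)
  occ_rows <- rowSums(mm$transition)
  expect_true(all(abs(occ_rows[ps$n_segments > 0 & occ_rows > 0] - 1) < 1e-12))
  expect_true(all(ps$gev >= 0) && mm$gev_total <= 1)
})

test_that("segment-level transition estimates converge to the jump chain", {
  P <- matrix(c(0, 0.6, 0.3, 0.1,
                0.2, 0, 0.5, 0.3,
                0.4, 0.3, 0, 0.3,
                0.1, 0.2, 0.7, 0), 4, 4, byrow = TRUE)
  set.seed(17)
  states <- integer(6000); states[1] <- 1L
  for (i in 2:6000) states[i] <- sample.int(4, 1, prob = P[states[i - 1], ])
  labels <- rep(states, times = sample(2:6, 6000, replace = TRUE))
  m <- metrics_from_labels(labels, fs = 500, k = 4)
  expect_lt(max(abs(m$transition - P)), 0.03)
})

test_that("total GEV is non-decreasing in k on the same maps", {
  p <- eeg_sim_params(duration_s = 6, seed = 23)
  sim <- simulate_eeg_subject(p)
  pk <- extract_gfp_peaks(compute_gfp(sim$recording))
  maps <- t(sim$recording$data[, pk])
  gevs <- vapply(2:6, function(k)
    modified_kmeans(maps, k, n_restarts = 10, seed = 3)$gev_total, 0)
  expect_true(all(diff(gevs) > -1e-6))
})
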