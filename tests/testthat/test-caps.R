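# CAP pipeline: z-scoring, sliding-window FC, cosine k-means with its
# brute-force oracle, frame assignment, Wilcoxon z-maps and temporal
# metrics.

test_that("per-ROI z-scoring standardises columns with the population SD", {
  tab <- roi_timeseries(matrix(c(1, 3, 5, 7), 2, 2), tr = 2)
  z <- zscore_roi(tab)
  expect_equal(unname(z$data), matrix(c(-1, 1, -1, 1), 2, 2))
  set.seed(1)
  big <- roi_timeseries(matrix(rnorm(300, 5, 3), 30, 10), tr = 2)
  zb <- zscore_roi(big)
  expect_lt(max(abs(colMeans(zb$data))), 1e-12)
  expect_lt(max(abs(sqrt(colMeans(zb$data^2)) - 1)), 1e-12)
  flat <- roi_timeseries(cbind(rnorm(5), rep(2, 5)), tr = 2,
                         roi_ids = c("ok", "flat"))
  err <- expect_error(zscore_roi(flat), class = "neurostate_error_zero_variance")
  expect_match(conditionMessage(err), "flat")
})

test_that("sliding-window FC has the right count and limiting behaviour", {
  set.seed(2)
  base <- rnorm(60)
  tab <- roi_timeseries(cbind(base, base * 2 + 1, rnorm(60)), tr = 2,
                        roi_ids = c("a", "b", "c"))
  fc <- sliding_window_fc(tab, window = 20, step = 5)
  expect_length(fc$matrices, floor((60 - 20) / 5) + 1)
  expect_true(all(vapply(fc$matrices, function(m) abs(m["a", "b"] - 1) < 1e-12, TRUE)))
  one <- sliding_window_fc(tab, window = 60)
  expect_equal(one$matrices[[1]], stats::cor(tab$data))
  expect_error(sliding_window_fc(tab, window = 2),
               class = "neurostate_error_window")
  expect_error(sliding_window_fc(tab, window = 61),
               class = "neurostate_error_window")
  # independent ROIs: weak off-diagonal correlations on average
  set.seed(3)
  noise <- roi_timeseries(matrix(rnorm(240 * 4), 240, 4), tr = 2)
  fcn <- sliding_window_fc(noise, window = 20, step = 10)
  offs <- unlist(lapply(fcn$matrices, function(m) abs(m[upper.tri(m)])))
  expect_lt(mean(offs), 0.25)
})


test_that("cosine k-means recovers orthogonal patterns and the brute-force optimum", {
  set.seed(4)
  pat <- t(qr.Q(qr(matrix(rnorm(12 * 3), 12, 3))))   # 3 orthonormal rows
  frames <- pat[rep(1:3, each = 8), ] * stats::runif(24, 0.5, 3)
  fit <- cap_cluster(frames, k = 3, n_restarts = 10, seed = 1)
  S <- abs(fit$centroids %*% t(pat))
  expect_true(all(apply(S, 2, max) > 0.999))
  expect_lt(fit$objective, 1e-9)

  frames10 <- matrix(rnorm(10 * 6), 10, 6)
  fit10 <- cap_cluster(frames10, k = 2, n_restarts = 50, seed = 2)
  U <- frames10 / sqrt(rowSums(frames10^2))
  expect_equal(fit10$objective, brute_force_cos2(U), tolerance = 1e-8)

  # duplicating every frame doubles the objective, same centroids
  dup <- cap_cluster(rbind(frames10, frames10), k = 2, n_restarts = 50, seed = 3)
  expect_equal(dup$objective, 2 * fit10$objective, tolerance = 1e-6)
  # assignment is invariant to positive rescaling of frames
  sc <- cap_cluster(frames10 * stats::runif(10, 0.5, 4), k = 2,
                    n_restarts = 50, seed = 2)
  expect_equal(sc$objective, fit10$objective, tolerance = 1e-8)
})

test_that("frame assignment is nearest-centroid with lower-index ties", {
  cs <- structure(list(centroids = rbind(c(1, 0), c(0, 1)), k = 2),
                  class = "cap_set")
  lab <- assign_frames(rbind(c(2, 0), c(0, 3), c(5, 5)), cs)
  expect_identical(lab, c(1L, 2L, 1L))   # equidistant -> lower index
  expect_error(assign_frames(matrix(1, 2, 3), cs),
               class = "neurostate_error_roi_mismatch")
})

test_that("CAP z-maps name and flag networks per construction", {
  atlas <- make_atlas(70)
  nets <- as.character(atlas)
  set.seed(5)
  n <- 40
  fr <- matrix(rnorm(n * 70, sd = 0.05), n, 70)
  fr[, nets == "DAN"] <- fr[, nets == "DAN"] + 1
  fr[, nets == "VAN"] <- fr[, nets == "VAN"] - 1
  zm <- cap_zscores(fr, rep(1L, n), atlas, k = 1)
  expect_identical(zm$names[1], "DAN+ VAN-")
  expect_true(all(zm$significant[1, nets == "DAN"]))
  expect_true(all(zm$significant[1, nets == "VAN"]))
  expect_false(any(zm$significant[1, !nets %in% c("DAN", "VAN")]))
  # single-network activation: the "-" network is simply the minimum-z one
  fr2 <- matrix(rnorm(n * 70, sd = 0.05), n, 70)
  fr2[, nets == "FPN"] <- fr2[, nets == "FPN"] + 1
  zm2 <- cap_zscores(fr2, rep(1L, n), atlas, k = 1)
  expect_match(zm2$names[1], "^FPN\\+ ")
  low <- sub(".* ", "", sub("-$", "", zm2$names[1]))
  expect_identical(unname(which.min(zm2$network_z[1, ])),
                   match(low, colnames(zm2$network_z)))
  # too few frames -> flagged, untested
  zm3 <- cap_zscores(fr[1:3, ], rep(1L, 3), atlas, k = 2)
  expect_false(any(zm3$tested))
})

test_that("symmetric noise stays nonsignificant after Bonferroni", {
  atlas <- make_atlas(21)
  hits <- vapply(1:40, function(s) {
    set.seed(s)
    fr <- matrix(stats::rnorm(30 * 21, sd = 0.2), 30, 21)
    zm <- cap_zscores(fr, rep(1L, 30), atlas, k = 1)
    any(zm$significant[1, ])
  }, TRUE)
  # family-wise false-positive rate is ~alpha; allow Monte-Carlo slack
  expect_gte(mean(!hits), 0.90)
})

test_that("temporal CAP metrics match hand-computed values and identities", {
  m1 <- cap_temporal_metrics(rep(3L, 100), tr = 2, k = 3)
  expect_equal(m1$fractional_occupancy, c(0, 0, 1))
  expect_equal(m1$dwell_time_s[3], 200)
  expect_equal(m1$appearance_rate_per_min[3], 0.3)
  expect_false(m1$present[1])
  expect_equal(m1$dwell_time_s[1], 0)

  alt <- cap_temporal_metrics(rep(c(1L, 2L), 50), tr = 2, k = 2)
  expect_equal(alt$fractional_occupancy, c(0.5, 0.5))
  expect_equal(alt$dwell_time_s, c(2, 2))
  expect_equal(alt$appearance_rate_per_min, c(15, 15))

  set.seed(6)
  rnd <- sample.int(5, 300, replace = TRUE)
  mr <- cap_temporal_metrics(rnd, tr = 2, k = 5)
  expect_equal(sum(mr$fractional_occupancy), 1, tolerance = 1e-12)
  expect_equal(mr$fractional_occupancy,
               mr$dwell_time_s * mr$appearance_rate_per_min / 60,
               tolerance = 1e-12)
  expect_error(cap_temporal_metrics(integer(0), tr = 2),
               class = "neurostate_error_empty")
})
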