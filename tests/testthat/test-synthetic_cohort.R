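# Synthetic generator: construction invariants, determinism, and agreement
# of realized dynamics with the configured ground truth.

test_that("canonical templates are average-referenced, unit-GFP and distinct", {
  for (nc in c(16, 32, 64)) {
    tm <- make_canonical_templates(nc)
    expect_equal(dim(tm), c(4L, nc))
    expect_equal(unname(rowMeans(tm)), rep(0, 4), tolerance = 1e-12)
    expect_equal(unname(sqrt(rowMeans(tm^2))), rep(1, 4), tolerance = 1e-12)
    cc <- stats::cor(t(tm))
    expect_true(all(abs(cc[upper.tri(cc)]) < 0.9))
  }
  expect_error(make_canonical_templates(5),
               class = "neurostate_error_too_few_channels")
})

test_that("template B is the left-right mirror of template A", {
  tm <- make_canonical_templates(32)
  pos <- attr(tm, "positions")
  mirror <- attr(pos, "mirror_index")
  # flip oracle: evaluate A on the mirrored channel order
  a_flipped <- tm["A", mirror]
  expect_gt(stats::cor(tm["B", ], a_flipped), 0.999)
})

test_that("EEG simulation is seed-deterministic and average-referenced", {
  p <- eeg_sim_params(duration_s = 4, seed = 11)
  s1 <- simulate_eeg_subject(p)
  s2 <- simulate_eeg_subject(p)
  expect_identical(s1$recording$data, s2$recording$data)
  expect_identical(s1$truth$labels, s2$truth$labels)
  expect_lt(max(abs(colMeans(s1$recording$data))), 1e-10)
  expect_error(
    simulate_eeg_subject(p, transition_matrix = diag(4)),
    class = "neurostate_error_diagonal_mass")
})

test_that("back-fitting the true templates recovers the state sequence at high SNR", {
  p <- eeg_sim_params(duration_s = 20, mean_duration_ms = 100, snr_db = 60,
                      seed = 7)
  sim <- simulate_eeg_subject(p)
  tset <- neurostate:::new_template_set(sim$truth$templates,
                                        labels = c("A", "B", "C", "D"))
  seg <- backfit(sim$recording, tset)
  expect_gt(mean(seg$labels == sim$truth$labels), 0.99)
})

test_that("uniform jump chain yields near-uniform empirical transitions", {
  p <- eeg_sim_params(duration_s = 180, seed = 5)
  sim <- simulate_eeg_subject(p)
  m <- metrics_from_labels(sim$truth$labels, p$fs, 4)
  off <- m$transition[row(m$transition) != col(m$transition)]
  expect_true(all(abs(off - 1 / 3) < 0.05))
})

test_that("noiseless BOLD frames sit exactly on their generating patterns", {
  bp <- bold_sim_params(noise_sd = 1e-12, seed = 3)
  bs <- simulate_bold_subject(bp)
  cs <- structure(list(centroids = bs$truth$patterns, k = 14),
                  class = "cap_set")
  lab <- assign_frames(bs$table$data, cs)
  expect_identical(lab, bs$truth$labels)
})

test_that("BOLD simulation is deterministic and honours the dwell target", {
  pat2 <- make_cap_patterns(make_atlas(100))[1:2, ]
  bp <- bold_sim_params(n_states = 2, mean_dwell_frames = 4, seed = 21)
  b1 <- simulate_bold_subject(bp, cap_patterns = pat2)
  b2 <- simulate_bold_subject(bp, cap_patterns = pat2)
  expect_identical(b1$table$data, b2$table$data)
  runs <- rle(b1$truth$labels)$lengths
  expect_lt(abs(mean(runs) - 4) / 4, 0.2)
})

test_that("default cohort has the configured composition and valid scores", {
  co <- simulate_cohort(cohort_effects(seed = 1),
                        eeg_sim_params(duration_s = 4),
                        bold_sim_params(n_frames = 60), mode = "metrics")
  expect_equal(nrow(co$cohort), 52 * 2)
  expect_equal(sum(co$cohort$group == "responder"), 24 * 2)
  expect_silent(neurostate:::validate_cohort(co$cohort))
  expect_true(all(co$cohort$mds_updrs3_total ==
                    round(co$cohort$mds_updrs3_total)))
  # metrics-mode cohorts are deterministic under the seed
  co2 <- simulate_cohort(cohort_effects(seed = 1),
                         eeg_sim_params(duration_s = 4),
                         bold_sim_params(n_frames = 60), mode = "metrics")
  expect_identical(co$cohort, co2$cohort)
  expect_identical(co$eeg_metrics, co2$eeg_metrics)
})

test_that("the MCID rule recovers the generator's group labels", {
  hits <- vapply(1:20, function(s) {
    co <- simulate_cohort(cohort_effects(seed = s),
                          eeg_sim_params(duration_s = 4),
                          bold_sim_params(n_frames = 60), mode = "metrics")
    lab <- stratify_responders(co$cohort)
    mean(lab$group == co$cohort$group)
  }, 0)
  expect_gte(mean(hits), 0.95)
})

test_that("responders' realized occurrence-D post/pre ratio tracks the factor", {
  co <- simulate_cohort(cohort_effects(seed = 2), eeg_sim_params(),
                        bold_sim_params(n_frames = 60), mode = "metrics")
  em <- co$eeg_metrics[co$eeg_metrics$group == "responder" &
                         co$eeg_metrics$state == 4, ]
  pre <- em$occurrence[em$timepoint == "pre"]
  post <- em$occurrence[em$timepoint == "post"]
  ratio <- mean(post / pre)
  expect_lt(abs(ratio - 1.25) / 1.25, 0.10)
})
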