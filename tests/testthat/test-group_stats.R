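# Stratification, routed univariate tests, 2x2 mixed ANOVA with its
# sums-of-squares oracle, simple effects and Spearman families.

test_that("the MCID rule stratifies strictly above 3.25 points", {
  co <- data.frame(subject_id = rep(c("S1", "S2", "S3"), each = 2),
                   group = "unknown", timepoint = rep(c("pre", "post"), 3),
                   mds_updrs3_total = c(40, 33, 36, 36, 30, 26),
                   tremor = 1, bradykinesia = 2, rigidity = 1, axial = 1,
                   pdq39 = 5)
  out <- stratify_responders(co)
  g <- out$group[match(c("S1", "S2", "S3"), out$subject_id)]
  expect_identical(g, c("responder", "nonresponder", "responder"))
  expect_error(stratify_responders(co[-1, ]),
               class = "neurostate_error_missing_timepoint")
  # exactly 3 points is not a response; 4 is
  co$mds_updrs3_total <- c(40, 37, 36, 32, 30, 30)
  out2 <- stratify_responders(co)
  expect_identical(out2$group[match(c("S1", "S2"), out2$subject_id)],
                   c("nonresponder", "responder"))
})

test_that("change rates follow their sign conventions and guard pre = 0", {
  expect_equal(change_rate(c(40, 20), c(30, 25)), c(0.25, -0.25))
  expect_equal(change_rate(c(40, 20), c(30, 25), type = "change"),
               c(-0.25, 0.25))
  expect_true(is.na(change_rate(0, 5)))
})

test_that("normality routing picks t for normal and rank tests for skewed data", {
  t_routes <- vapply(1:400, function(s) {
    set.seed(s)
    route_and_test(rnorm(30), rnorm(30))$normal_route
  }, TRUE)
  expect_gte(mean(t_routes), 0.9)
  np_routes <- vapply(1:200, function(s) {
    set.seed(s)
    isFALSE(route_and_test(exp(rnorm(30, sd = 1.5)),
                           exp(rnorm(30, sd = 1.5)))$normal_route)
  }, TRUE)
  expect_gte(mean(np_routes), 0.9)
})

test_that("degenerate inputs yield flagged conventions, not errors", {
  r <- route_and_test(c(3, 3, 3, 3), c(3, 3, 3, 3), paired = TRUE)
  expect_match(r$test, "degenerate")
  expect_identical(r$p, 1)
  r2 <- route_and_test(c(5, 5, 5), c(2, 2, 2), paired = TRUE)
  expect_match(r2$test, "degenerate")
  expect_identical(r2$p, 0)
})

test_that("mixed ANOVA matches the independent sums-of-squares oracle", {
  set.seed(11)
  for (rep in 1:3) {
    n1 <- 4; n2 <- 5
    subj <- c(paste0("R", 1:n1), paste0("N", 1:n2))
    df <- expand.grid(subject = subj, time = c("pre", "post"),
                      stringsAsFactors = FALSE)
    df$group <- ifelse(grepl("^R", df$subject), "g1", "g2")
    df$value <- rnorm(nrow(df), mean = ifelse(df$group == "g1", 1, 0) +
                        ifelse(df$time == "post", 0.5, 0))
    a <- mixed_anova_2x2(df$value, df$group, df$time, df$subject)
    o <- anova_oracle(df$value, df$group, df$time, df$subject)
    expect_equal(a$F, unname(o$F[c("group", "time", "int")]), tolerance = 1e-8)
    expect_equal(a$ss_effect, unname(o$ss[c("group", "time", "int")]),
                 tolerance = 1e-8)
    expect_equal(a$eta_p2,
                 unname(c(o$ss["group"] / (o$ss["group"] + o$ss["bet_err"]),
                          o$ss["time"] / (o$ss["time"] + o$ss["wth_err"]),
                          o$ss["int"] / (o$ss["int"] + o$ss["wth_err"]))),
                 tolerance = 1e-8)
    # conservation: stratum SS add up to the corrected total
    expect_equal(attr(a, "ss_total"),
                 sum((df$value - mean(df$value))^2), tolerance = 1e-9)
  }
})

test_that("mixed ANOVA nulls and pure crossover behave as designed", {
  subj <- paste0("S", 1:8)
  df <- expand.grid(subject = subj, time = c("pre", "post"),
                    stringsAsFactors = FALSE)
  df$group <- rep(rep(c("a", "b"), each = 4), 2)
  offs <- stats::setNames(1:8, subj)
  df$value <- offs[df$subject]          # subject offsets only
  a <- mixed_anova_2x2(df$value, df$group, df$time, df$subject)
  expect_equal(a$F[a$effect == "time"], 0)
  expect_equal(a$F[a$effect == "group:time"], 0)
  # pure crossover: group means +/- d swap across time, no noise
  d <- 0.7
  df$value <- ifelse((df$group == "a") == (df$time == "pre"), d, -d) +
    offs[df$subject]
  a2 <- mixed_anova_2x2(df$value, df$group, df$time, df$subject)
  expect_equal(a2$eta_p2[a2$effect == "group:time"], 1)
  expect_error(mixed_anova_2x2(df$value[-1], df$group[-1], df$time[-1],
                               df$subject[-1]),
               class = "neurostate_error_unbalanced")
})

test_that("simple effects are Bonferroni-scaled and detect the injected contrast", {
  set.seed(21)
  n <- 30
  subj <- paste0("S", 1:(2 * n))
  df <- expand.grid(subject = subj, time = c("pre", "post"),
                    stringsAsFactors = FALSE)
  df$group <- rep(rep(c("resp", "non"), each = n), 2)
  df$value <- rnorm(nrow(df))
  df$value[df$group == "resp" & df$time == "post"] <-
    df$value[df$group == "resp" & df$time == "post"] + 3
  se <- simple_effects(df$value, df$group, df$time, df$subject)
  resp_row <- grepl("^resp:", se$contrast)
  expect_lt(se$p_bonferroni[resp_row], 0.05)
  expect_gt(min(se$p_bonferroni[grepl("^non:", se$contrast)]), 0.05)
  expect_equal(se$p_bonferroni, pmin(1, se$p * 4))
  se1 <- simple_effects(df$value, df$group, df$time, df$subject,
                        family_size = 1)
  expect_equal(se1$p_bonferroni, se1$p)
})

test_that("family-wise error of the corrected simple effects stays controlled", {
  set.seed(31)
  n <- 12
  subj <- paste0("S", 1:(2 * n))
  base <- expand.grid(subject = subj, time = c("pre", "post"),
                      stringsAsFactors = FALSE)
  base$group <- rep(rep(c("a", "b"), each = n), 2)
  fw <- vapply(1:1000, function(i) {
    v <- rnorm(nrow(base))
    any(simple_effects(v, base$group, base$time, base$subject)$p_bonferroni
        < 0.05)
  }, TRUE)
  # Bonferroni keeps FWER at or below alpha; allow Monte-Carlo slack
  expect_lte(mean(fw), 0.065)
})

test_that("Spearman families match the rank-Pearson oracle and cor.test", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3)
  expect_equal(spearman_family(data.frame(x = x), data.frame(y = x))$rho, 1)
  expect_equal(spearman_family(data.frame(x = x),
                               data.frame(y = -x^3))$rho, -1)
  set.seed(41)
  a <- rnorm(20); b <- 0.4 * a + rnorm(20)
  res <- spearman_family(data.frame(a = a), data.frame(b = b))
  oracle <- stats::cor(rank(a), rank(b))
  expect_equal(res$rho, oracle, tolerance = 1e-12)
  expect_equal(res$rho,
               unname(suppressWarnings(
                 stats::cor.test(a, b, method = "spearman")$estimate)),
               tolerance = 1e-12)
  expect_error(spearman_family(data.frame(a = rep(1, 6)), data.frame(b = a[1:6])),
               class = "neurostate_error_constant_variable")
  fam <- spearman_family(data.frame(a = a, a2 = -a), data.frame(b = b))
  expect_equal(fam$p_bonferroni, pmin(1, fam$p * 2))
})

test_that("interaction p-values are calibrated under the null generator", {
  hits <- vapply(1:250, function(s) {
    co <- simulate_cohort(null_effects(s),
                          eeg_sim_params(duration_s = 10),
                          bold_sim_params(n_frames = 30), mode = "metrics")
    em <- co$eeg_metrics[co$eeg_metrics$state == 3, ]
    a <- mixed_anova_2x2(em$occurrence, em$group, em$timepoint, em$subject_id)
    a$p[a$effect == "group:time"] < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.01)
  expect_lte(mean(hits), 0.09)
})
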