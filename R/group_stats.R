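# Responder stratification, change rates, normality-routed univariate
# tests, 2x2 mixed ANOVA with partial eta squared, Bonferroni simple
# effects, and Spearman correlation families.

#' Stratify a cohort into responders and nonresponders
#'
#' A subject is a responder iff their MDS-UPDRS III total decreased by
#' strictly more than `threshold` points from pre to post (the minimal
#' clinically important difference; with integer scores `> 3.25` is
#' equivalent to `>= 4`).
#'
#' @param cohort a cohort data.frame (see [read_cohort()]); every subject
#'   must have a pre and a post row.
#' @param threshold MCID in points (default 3.25).
#' @return The cohort with `group` filled in; attribute `summary` holds the
#'   counts and the responder percentage.
#' @export
stratify_responders <- function(cohort, threshold = 3.25) {
  if (threshold <= 0)
    ns_stop("neurostate_error_bad_threshold", "threshold must be > 0")
  wide <- merge(cohort[cohort$timepoint == "pre", c("subject_id", "mds_updrs3_total")],
                cohort[cohort$timepoint == "post", c("subject_id", "mds_updrs3_total")],
                by = "subject_id", suffixes = c("_pre", "_post"), all = TRUE)
  if (anyNA(wide))
    ns_stop("neurostate_error_missing_timepoint",
            "subject(s) missing a timepoint: %s",
            paste(wide$subject_id[!stats::complete.cases(wide)], collapse = ", "))
  wide$group <- ifelse(wide$mds_updrs3_total_pre - wide$mds_updrs3_total_post >
                         threshold, "responder", "nonresponder")
  out <- cohort
  out$group <- wide$group[match(out$subject_id, wide$subject_id)]
  n_resp <- sum(wide$group == "responder")
  attr(out, "summary") <- list(
    n_responders = n_resp,
    n_nonresponders = nrow(wide) - n_resp,
    responder_pct = 100 * n_resp / nrow(wide))
  out
}

#' Pre/post change rates
#'
#' `reduction_rate = (pre - post) / pre` (clinical improvement),
#' `change_rate = (post - pre) / pre` (neural change). Undefined (NA) when
#' `pre == 0`.
#'
#' @param pre,post numeric vectors.
#' @param type `"reduction"` or `"change"`.
#' @return numeric vector of rates.
#' @export
change_rate <- function(pre, post, type = c("reduction", "change")) {
  type <- match.arg(type)
  num <- if (type == "reduction") pre - post else post - pre
  ifelse(pre == 0, NA_real_, num / pre)
}

#' Normality-routed univariate comparison
#'
#' Shapiro-Wilk at `alpha_normal` decides the route: normal data go to a
#' paired/independent t test, non-normal to the Wilcoxon signed-rank /
#' Mann-Whitney U test. For paired comparisons normality is assessed on the
#' differences. Degenerate zero-variance (paired) data yield a flagged
#' non-significant result (p = 1) rather than an error.
#'
#' @param x,y numeric samples (paired vectors or two groups), n >= 3 each.
#' @param paired logical.
#' @param alpha_normal Shapiro-Wilk level (default 0.05).
#' @return list: `test` (name), `statistic`, `p`, `normal_route`, `note`.
#' @export
route_and_test <- function(x, y, paired = FALSE, alpha_normal = 0.05) {
  if (length(x) < 3 || length(y) < 3)
    ns_stop("neurostate_error_small_sample", "need n >= 3 per sample")
  if (paired && length(x) != length(y))
    ns_stop("neurostate_error_pair_length", "paired samples differ in length")
  if (paired) {
    d <- x - y
    if (all(d == d[1])) {
      if (d[1] == 0)
        return(list(test = "degenerate (zero-variance differences)",
                    statistic = NA_real_, p = 1, normal_route = NA,
                    note = "all paired differences identical and zero; p = 1 by convention"))
      # constant nonzero shift: report it as an exact shift
      return(list(test = "degenerate (constant nonzero differences)",
                  statistic = d[1], p = 0, normal_route = NA,
                  note = "all paired differences equal a nonzero constant"))
    }
    normal <- stats::shapiro.test(d)$p.value > alpha_normal
    if (normal) {
      tt <- stats::t.test(x, y, paired = TRUE)
      return(list(test = "paired t", statistic = unname(tt$statistic),
                  p = tt$p.value, normal_route = TRUE, note = NULL))
    }
    ties <- anyDuplicated(abs(d[d != 0])) > 0
    wt <- suppressWarnings(stats::wilcox.test(
      x, y, paired = TRUE, exact = length(d) <= 25 && !ties, correct = TRUE))
    return(list(test = "Wilcoxon signed-rank", statistic = unname(wt$statistic),
                p = wt$p.value, normal_route = FALSE,
                note = if (ties) "tie correction applied" else NULL))
  }
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    return(list(test = "degenerate (both samples constant)",
                statistic = NA_real_, p = if (x[1] == y[1]) 1 else 0,
                normal_route = NA,
                note = "both samples constant; p by convention"))
  normal <- stats::shapiro.test(x)$p.value > alpha_normal &&
    stats::shapiro.test(y)$p.value > alpha_normal
  if (normal) {
    tt <- stats::t.test(x, y)
    return(list(test = "independent t", statistic = unname(tt$statistic),
                p = tt$p.value, normal_route = TRUE, note = NULL))
  }
  ties <- anyDuplicated(c(x, y)) > 0
  wt <- suppressWarnings(stats::wilcox.test(
    x, y, exact = (length(x) + length(y)) <= 50 && !ties, correct = TRUE))
  list(test = "Mann-Whitney U", statistic = unname(wt$statistic),
       p = wt$p.value, normal_route = FALSE,
       note = if (ties) "tie correction applied" else NULL)
}

#' Two-by-two mixed ANOVA with partial eta squared
#'
#' Group (2 levels, between subjects) by time (2 levels, within subjects)
#' analysis of variance, fitted with `stats::aov` using an
#' `Error(subject)` stratum. Partial eta squared uses the error stratum
#' matching each effect: between-subject error for the group effect,
#' within-subject error for time and the interaction.
#'
#' @param value numeric outcomes, one per observation.
#' @param group between-subject factor (2 levels).
#' @param time within-subject factor (2 levels, both per subject).
#' @param subject subject identifiers.
#' @return data.frame with one row per effect (`group`, `time`,
#'   `group:time`): `F`, `df1`, `df2`, `p`, `eta_p2`, `ss_effect`,
#'   `ss_error`. Attribute `ss_total` holds the corrected total sum of
#'   squares for conservation checks.
#' @export
mixed_anova_2x2 <- function(value, group, time, subject) {
  df <- data.frame(value = value, group = factor(group),
                   time = factor(time), subject = factor(subject))
  if (nlevels(df$group) != 2 || nlevels(df$time) != 2)
    ns_stop("neurostate_error_design", "group and time must each have 2 levels")
  counts <- table(df$subject, df$time)
  if (any(counts != 1))
    ns_stop("neurostate_error_unbalanced",
            "every subject needs exactly one observation per timepoint")
  per_group <- table(unique(df[, c("subject", "group")])$group)
  if (any(per_group < 2))
    ns_stop("neurostate_error_group_size", "need >= 2 subjects per group")
  a <- stats::aov(value ~ group * time + Error(subject), data = df)
  s <- summary(a)
  btw <- s[["Error: subject"]][[1]]
  wth <- s[["Error: Within"]][[1]]
  pick <- function(tab, row) {
    i <- grep(paste0("^", row, "\\s*$"), trimws(rownames(tab)))
    tab[i, , drop = FALSE]
  }
  g <- pick(btw, "group"); gr <- pick(btw, "Residuals")
  t1 <- pick(wth, "time"); i1 <- pick(wth, "group:time"); wr <- pick(wth, "Residuals")
  ss_scale <- sum((df$value - mean(df$value))^2)
  mk <- function(eff, tab, err) {
    ss_e <- tab[1, "Sum Sq"]; ss_r <- err[1, "Sum Sq"]
    if (ss_e + ss_r <= 1e-12 * max(ss_scale, 1)) {
      # degenerate stratum (e.g. zero within-subject variance): flagged null
      return(data.frame(effect = eff, F = 0, df1 = tab[1, "Df"],
                        df2 = err[1, "Df"], p = 1, eta_p2 = 0,
                        ss_effect = ss_e, ss_error = ss_r))
    }
    data.frame(effect = eff, F = ss_e / tab[1, "Df"] / (ss_r / err[1, "Df"]),
               df1 = tab[1, "Df"], df2 = err[1, "Df"],
               p = stats::pf(ss_e / tab[1, "Df"] / (ss_r / err[1, "Df"]),
                             tab[1, "Df"], err[1, "Df"], lower.tail = FALSE),
               eta_p2 = ss_e / (ss_e + ss_r),
               ss_effect = ss_e, ss_error = ss_r)
  }
  out <- rbind(mk("group", g, gr), mk("time", t1, wr), mk("group:time", i1, wr))
  attr(out, "ss_total") <- g[1, "Sum Sq"] + gr[1, "Sum Sq"] + t1[1, "Sum Sq"] +
    i1[1, "Sum Sq"] + wr[1, "Sum Sq"]
  out
}

#' Bonferroni-corrected simple effects after a 2x2 mixed ANOVA
#'
#' Four contrasts: pre vs post within each group (paired) and group vs
#' group at each timepoint (independent), each routed through
#' [route_and_test()], with p-values multiplied by `family_size` and capped
#' at 1.
#'
#' @inheritParams mixed_anova_2x2
#' @param family_size Bonferroni family size (default 4, the four
#'   contrasts).
#' @return data.frame: `contrast`, `test`, `statistic`, `p`,
#'   `p_bonferroni`.
#' @export
simple_effects <- function(value, group, time, subject, family_size = 4) {
  df <- data.frame(value = value, group = as.character(group),
                   time = as.character(time), subject = as.character(subject))
  gl <- sort(unique(df$group)); tl <- c("pre", "post")
  if (!all(df$time %in% tl)) tl <- sort(unique(df$time))
  get <- function(g, t) {
    sub <- df[df$group == g & df$time == t, ]
    sub$value[order(sub$subject)]
  }
  rows <- list()
  for (g in gl) {
    r <- route_and_test(get(g, tl[1]), get(g, tl[2]), paired = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      contrast = sprintf("%s: %s vs %s", g, tl[1], tl[2]),
      test = r$test, statistic = r$statistic, p = r$p)
  }
  for (t in tl) {
    r <- route_and_test(get(gl[1], t), get(gl[2], t), paired = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      contrast = sprintf("%s: %s vs %s", t, gl[1], gl[2]),
      test = r$test, statistic = r$statistic, p = r$p)
  }
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p * family_size)
  out
}

spearman_rho_t <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5)
    ns_stop("neurostate_error_small_sample", "Spearman needs n >= 5 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    ns_stop("neurostate_error_constant_variable",
            "Spearman correlation undefined for a constant variable")
  rho <- stats::cor(rank(x), rank(y))
  tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), n - 2)
  list(rho = rho, p = min(1, p), n = n)
}

#' Spearman correlation family with Bonferroni correction
#'
#' All pairs of columns of `x` and `y`: Spearman's rho via average-rank
#' Pearson correlation, p from the t approximation, Bonferroni over the
#' declared family (default: the number of pairs).
#'
#' @param x,y data.frames (or named lists) of paired numeric variables.
#' @param family_size explicit Bonferroni family size; defaults to
#'   `ncol(x) * ncol(y)`.
#' @return data.frame: `x_var`, `y_var`, `rho`, `p`, `p_bonferroni`, `n`.
#' @export
spearman_family <- function(x, y, family_size = NULL) {
  x <- as.data.frame(x); y <- as.data.frame(y)
  if (is.null(family_size)) family_size <- ncol(x) * ncol(y)
  rows <- list()
  for (i in seq_along(x)) for (j in seq_along(y)) {
    r <- spearman_rho_t(x[[i]], y[[j]])
    rows[[length(rows) + 1L]] <- data.frame(
      x_var = names(x)[i], y_var = names(y)[j],
      rho = r$rho, p = r$p, p_bonferroni = min(1, r$p * family_size),
      n = r$n)
  }
  do.call(rbind, rows)
}
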