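# Responder-vs-nonresponder prediction from baseline features: binary SVM
# under repeated, stratified, nested cross-validation with inner-fold
# hyperparameter search and decision-threshold optimisation.

FEATURE_SETS <- list(
  clinical = "mds_updrs3_total",
  eeg = c("ms_C_occurrence", "ms_D_occurrence"),
  fmri = "cap_DANpVANm_dwell",
  multimodal = c("ms_C_occurrence", "ms_D_occurrence", "cap_DANpVANm_dwell"))

#' Assemble the baseline feature table
#'
#' Inner-joins the baseline (pre) modalities on subject id: MDS-UPDRS III
#' total, microstate C and D occurrence, and the "DAN+ VAN-" CAP dwell
#' time. Subjects missing any modality are dropped and recorded in the
#' `excluded` attribute.
#'
#' @param microstate_baseline data.frame with `subject_id`,
#'   `ms_C_occurrence`, `ms_D_occurrence`.
#' @param cap_baseline data.frame with `subject_id`, `cap_DANpVANm_dwell`.
#' @param cohort cohort data.frame with pre rows and resolved `group`
#'   labels (responder / nonresponder).
#' @return data.frame with one row per subject: the four features and
#'   `label` (factor, responder = positive class). Attribute `excluded`
#'   lists dropped subjects.
#' @export
build_feature_table <- function(microstate_baseline, cap_baseline, cohort) {
  pre <- cohort[cohort$timepoint == "pre",
                c("subject_id", "group", "mds_updrs3_total")]
  if (!all(pre$group %in% c("responder", "nonresponder")))
    ns_stop("neurostate_error_unlabeled",
            "cohort groups must be resolved before building features")
  ft <- merge(merge(pre, microstate_baseline, by = "subject_id"),
              cap_baseline, by = "subject_id")
  if (nrow(ft) == 0)
    ns_stop("neurostate_error_empty_join", "no subjects shared across modalities")
  excluded <- setdiff(pre$subject_id, ft$subject_id)
  ft$label <- factor(ft$group, levels = c("nonresponder", "responder"))
  ft$group <- NULL
  attr(ft, "excluded") <- excluded
  ft
}

stratified_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

# sensitivity + specificity over candidate thresholds on decision values
# (positive class = second factor level); returns the best threshold and J
best_threshold <- function(dv, y) {
  pos <- y == levels(y)[2]
  cand <- sort(unique(dv))
  cand <- c(cand[1] - 1, (cand[-1] + cand[-length(cand)]) / 2,
            cand[length(cand)] + 1)
  best <- list(threshold = 0, j = -Inf)
  for (th in cand) {
    pred <- dv > th
    sens <- sum(pred & pos) / sum(pos)
    spec <- sum(!pred & !pos) / sum(!pos)
    if (sens + spec > best$j + 1e-12) best <- list(threshold = th, j = sens + spec)
  }
  best
}

svm_decision <- function(fit, x, positive) {
  p <- stats::predict(fit, x, decision.values = TRUE)
  dv <- drop(attr(p, "decision.values"))
  cn <- colnames(attr(p, "decision.values"))
  # libsvm's decision value is positive for the class named first
  if (!startsWith(cn, paste0(positive, "/"))) dv <- -dv
  dv
}

fit_svm <- function(x, y, cost, gamma, kernel) {
  cw <- length(y) / (2 * table(y))
  e1071::svm(x, y, kernel = kernel, cost = cost, gamma = gamma,
             class.weights = cw, scale = FALSE)
}

# inner-CV objective for one (cost, gamma): pooled held-out decision
# values -> best achievable Youden J
inner_objective <- function(x, y, cost, gamma, kernel, inner_folds) {
  dv <- numeric(length(y))
  for (f in seq_len(max(inner_folds))) {
    tr <- inner_folds != f
    if (length(unique(y[tr])) < 2) return(list(j = -Inf))
    fit <- fit_svm(x[tr, , drop = FALSE], y[tr], cost, gamma, kernel)
    dv[!tr] <- svm_decision(fit, x[!tr, , drop = FALSE], levels(y)[2])
  }
  c(best_threshold(dv, y), list(dv = dv))
}

search_grid <- function(x, y, kernel, inner_folds, grid) {
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    r <- inner_objective(x, y, grid$cost[i], grid$gamma[i], kernel, inner_folds)
    if (is.null(best) || r$j > best$j + 1e-12)
      best <- list(cost = grid$cost[i], gamma = grid$gamma[i],
                   j = r$j, threshold = r$threshold)
  }
  best
}

# expected-improvement search over log10(cost), log10(gamma multiplier)
search_bayes <- function(x, y, kernel, inner_folds, gamma0, n_eval = 30) {
  lo <- c(-2, -3); hi <- c(4, 3)
  n_init <- 8
  pts <- cbind(stats::runif(n_init, lo[1], hi[1]),
               stats::runif(n_init, lo[2], hi[2]))
  evals <- apply(pts, 1, function(p)
    inner_objective(x, y, 10^p[1], gamma0 * 10^p[2], kernel, inner_folds)$j)
  kern <- function(A, B) {
    d2 <- outer(A[, 1], B[, 1], "-")^2 + outer(A[, 2], B[, 2], "-")^2
    exp(-d2 / (2 * 1.5^2))
  }
  while (nrow(pts) < n_eval) {
    mu0 <- mean(evals); sd0 <- max(stats::sd(evals), 1e-3)
    z <- (evals - mu0) / sd0
    K <- kern(pts, pts) + diag(1e-4, nrow(pts))
    Ki <- solve(K)
    cand <- cbind(stats::runif(400, lo[1], hi[1]), stats::runif(400, lo[2], hi[2]))
    Ks <- kern(cand, pts)
    mu <- Ks %*% (Ki %*% z)
    var <- pmax(1 - rowSums((Ks %*% Ki) * Ks), 1e-9)
    s <- sqrt(var)
    imp <- mu - max(z)
    ei <- imp * stats::pnorm(imp / s) + s * stats::dnorm(imp / s)
    p <- cand[which.max(ei), ]
    pts <- rbind(pts, p)
    evals <- c(evals, inner_objective(x, y, 10^p[1], gamma0 * 10^p[2],
                                      kernel, inner_folds)$j)
  }
  b <- pts[which.max(evals), ]
  r <- inner_objective(x, y, 10^b[1], gamma0 * 10^b[2], kernel, inner_folds)
  list(cost = 10^b[1], gamma = gamma0 * 10^b[2], j = r$j,
       threshold = r$threshold)
}

#' Repeated nested cross-validated SVM
#'
#' Per repetition: stratified outer folds; within each outer training set,
#' features are standardised (training statistics only), hyperparameters
#' (cost and RBF kernel width) are selected by an inner stratified
#' cross-validation, and the decision threshold is chosen on the pooled
#' inner held-out decision values by maximising sensitivity + specificity
#' (Youden's J). Outer-fold predictions are pooled into repetition-level
#' accuracy, sensitivity and specificity (responder = positive class), and
#' the report carries their mean and standard error over repetitions.
#'
#' @param features data.frame from [build_feature_table()], or any
#'   data.frame with a `label` factor column and numeric feature columns.
#' @param feature_set one of `"clinical"`, `"eeg"`, `"fmri"`,
#'   `"multimodal"`, or a character vector of feature column names.
#' @param outer,inner numbers of outer and inner folds (default 5).
#' @param repetitions independent repetitions with re-randomised splits
#'   (default 5).
#' @param seed RNG seed covering fold draws and the search.
#' @param kernel SVM kernel (default `"radial"`).
#' @param tune `"grid"` (log-spaced grid, deterministic, default) or
#'   `"bayes"` (expected-improvement search, 30 evaluations).
#' @param grid_size per-axis size of the log grid (default 7).
#' @param folds optional precomputed fold assignment matrix (subjects x
#'   repetitions) to share splits across feature sets.
#' @return list of class `classifier_report`: `summary` (mean and SE of
#'   the three metrics, percent), `per_repetition`, `chosen` (per outer
#'   fold), `feature_set`, `folds`.
#' @export
nested_cv_svm <- function(features, feature_set = "multimodal",
                          outer = 5, inner = 5, repetitions = 5,
                          seed = NULL, kernel = "radial",
                          tune = c("grid", "bayes"), grid_size = 7,
                          folds = NULL) {
  tune <- match.arg(tune)
  cols <- if (length(feature_set) == 1 && feature_set %in% names(FEATURE_SETS))
    FEATURE_SETS[[feature_set]] else feature_set
  missing_cols <- setdiff(cols, names(features))
  if (length(missing_cols))
    ns_stop("neurostate_error_missing_features",
            "feature column(s) absent: %s", paste(missing_cols, collapse = ", "))
  X <- as.matrix(features[, cols, drop = FALSE])
  y <- features$label
  if (anyNA(X)) ns_stop("neurostate_error_missing_values", "features contain NA")
  n <- nrow(X)
  if (n < 10) ns_stop("neurostate_error_small_sample", "need >= 10 subjects for CV")
  if (min(table(y)) < outer)
    ns_stop("neurostate_error_class_size",
            "the smaller class must have at least `outer` members")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(folds)) {
    folds <- vapply(seq_len(repetitions),
                    function(r) stratified_folds(y, outer), integer(n))
  }
  gamma0 <- 1 / ncol(X)
  gr <- if (kernel == "linear") {
    # libsvm ignores gamma for the linear kernel; search cost only, over a
    # bounded range (huge costs on near-separable data stall the optimiser)
    expand.grid(cost = 10^seq(-2, 2, length.out = grid_size), gamma = gamma0)
  } else {
    expand.grid(cost = 10^seq(-2, 4, length.out = grid_size),
                gamma = gamma0 * 10^seq(-3, 3, length.out = grid_size))
  }
  per_rep <- NULL; chosen <- NULL
  for (rep_i in seq_len(repetitions)) {
    fold <- folds[, rep_i]
    pred <- logical(n); touched <- rep(FALSE, n)
    for (f in seq_len(outer)) {
      tr <- which(fold != f); te <- which(fold == f)
      stopifnot(length(intersect(tr, te)) == 0)   # leakage audit
      mu <- colMeans(X[tr, , drop = FALSE])
      sdv <- apply(X[tr, , drop = FALSE], 2, stats::sd)
      sdv[sdv == 0] <- 1
      Ztr <- scale(X[tr, , drop = FALSE], mu, sdv)
      Zte <- scale(X[te, , drop = FALSE], mu, sdv)
      inner_fold <- stratified_folds(y[tr], inner)
      sel <- if (tune == "grid") search_grid(Ztr, y[tr], kernel, inner_fold, gr)
             else search_bayes(Ztr, y[tr], kernel, inner_fold, gamma0)
      fit <- fit_svm(Ztr, y[tr], sel$cost, sel$gamma, kernel)
      dv <- svm_decision(fit, Zte, levels(y)[2])
      pred[te] <- dv > sel$threshold
      touched[te] <- TRUE
      chosen <- rbind(chosen, data.frame(repetition = rep_i, fold = f,
                                         cost = sel$cost, gamma = sel$gamma,
                                         threshold = sel$threshold))
    }
    stopifnot(all(touched))
    pos <- y == levels(y)[2]
    acc <- mean(pred == pos) * 100
    sens <- sum(pred & pos) / sum(pos) * 100
    spec <- sum(!pred & !pos) / sum(!pos) * 100
    per_rep <- rbind(per_rep, data.frame(repetition = rep_i, accuracy = acc,
                                         sensitivity = sens, specificity = spec))
  }
  summ <- data.frame(
    metric = c("accuracy", "sensitivity", "specificity"),
    mean = c(mean(per_rep$accuracy), mean(per_rep$sensitivity),
             mean(per_rep$specificity)),
    se = c(stats::sd(per_rep$accuracy), stats::sd(per_rep$sensitivity),
           stats::sd(per_rep$specificity)) / sqrt(repetitions))
  structure(list(summary = summ, per_repetition = per_rep, chosen = chosen,
                 feature_set = paste(cols, collapse = "+"), folds = folds,
                 n = n),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report> features: %s (n = %d)\n", x$feature_set, x$n))
  with(x$summary,
       cat(sprintf("  %-12s %5.2f +/- %.2f %%\n", metric, mean, se), sep = ""))
  invisible(x)
}

#' Compare feature sets under identical splits
#'
#' Runs [nested_cv_svm()] once per feature set with the same fold
#' assignments (drawn once from `seed`) and ranks the sets by mean
#' accuracy.
#'
#' @param features the full feature table.
#' @param sets character vector of feature-set tags (default all four).
#' @inheritParams nested_cv_svm
#' @return list: `reports` (named), `ranking` (data.frame sorted by mean
#'   accuracy, descending).
#' @export
compare_feature_sets <- function(features,
                                 sets = c("clinical", "eeg", "fmri", "multimodal"),
                                 outer = 5, inner = 5, repetitions = 5,
                                 seed = NULL, kernel = "radial",
                                 tune = c("grid", "bayes"), grid_size = 7) {
  tune <- match.arg(tune)
  if (!is.null(seed)) set.seed(seed)
  shared_folds <- vapply(seq_len(repetitions),
                         function(r) stratified_folds(features$label, outer),
                         integer(nrow(features)))
  reports <- lapply(stats::setNames(sets, sets), function(fs)
    nested_cv_svm(features, fs, outer = outer, inner = inner,
                  repetitions = repetitions, kernel = kernel, tune = tune,
                  grid_size = grid_size, folds = shared_folds))
  acc <- vapply(reports, function(r) r$summary$mean[1], 0)
  ranking <- data.frame(feature_set = names(acc), mean_accuracy = unname(acc))
  ranking <- ranking[order(-ranking$mean_accuracy), ]
  list(reports = reports, ranking = ranking)
}
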