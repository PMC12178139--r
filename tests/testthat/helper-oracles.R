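# Independent brute-force oracles shared by the unit and acceptance tests.
# Each recomputes a quantity by exhaustive enumeration or direct formula,
# independently of the package's implementation path.

# independent brute-force oracle: best polarity-invariant 2-partition GEV
brute_force_gev2 <- function(maps) {
  X <- sweep(maps, 1, rowMeans(maps))
  g2 <- rowSums(X^2)
  n <- nrow(X)
  best <- 0
  for (code in 0:(2^(n - 1) - 1)) {
    assign <- c(0L, as.integer(intToBits(code))[seq_len(n - 1)]) + 1L
    if (length(unique(assign)) < 2) next
    tot <- 0
    for (j in 1:2) {
      Xi <- X[assign == j, , drop = FALSE]
      ev <- eigen(crossprod(Xi), symmetric = TRUE)
      v <- ev$vectors[, 1]
      tot <- tot + sum((Xi %*% v)^2 / rowSums(Xi^2) * g2[assign == j])
    }
    best <- max(best, tot / sum(g2))
  }
  best
}

# brute-force minimum of the cosine k-means objective over 2-partitions
brute_force_cos2 <- function(U) {
  n <- nrow(U)
  best <- Inf
  for (code in 0:(2^(n - 1) - 1)) {
    assign <- c(0L, as.integer(intToBits(code))[seq_len(n - 1)]) + 1L
    if (length(unique(assign)) < 2) next
    tot <- 0
    for (j in 1:2) {
      m <- colMeans(U[assign == j, , drop = FALSE])
      cc <- m / sqrt(sum(m^2))
      tot <- tot + sum(1 - U[assign == j, , drop = FALSE] %*% cc)
    }
    best <- min(best, tot)
  }
  best
}

# independent sums-of-squares oracle for the balanced-within 2x2 design
anova_oracle <- function(value, group, time, subject) {
  df <- data.frame(value, group = as.character(group),
                   time = as.character(time), subject = as.character(subject))
  subj <- unique(df[, c("subject", "group")])
  means <- tapply(df$value, df$subject, mean)
  diffs <- tapply(df$value[df$time == "post"], df$subject[df$time == "post"],
                  identity) -
    tapply(df$value[df$time == "pre"], df$subject[df$time == "pre"], identity)
  means <- means[subj$subject]; diffs <- diffs[subj$subject]
  n <- nrow(subj); g <- subj$group
  grand <- mean(df$value)
  # between stratum on subject means (2 observations each)
  ss_group <- 2 * sum(tapply(means, g, function(m) length(m) * (mean(m) - mean(means))^2))
  ss_bet_err <- 2 * sum((means - ave(means, g))^2)
  # within stratum on half-differences
  h <- diffs / 2
  ss_time_full <- 2 * n * mean(h)^2
  # Type I: time fitted before group:time, weighted means
  ss_time <- 2 * n * mean(h)^2
  ss_int <- 2 * sum(tapply(h, g, function(x) length(x) * mean(x)^2)) - ss_time
  ss_wth_err <- 2 * sum((h - ave(h, g))^2)
  n_g <- table(g)
  list(ss = c(group = ss_group, time = ss_time, int = ss_int,
              bet_err = ss_bet_err, wth_err = ss_wth_err),
       F = c(group = (ss_group / 1) / (ss_bet_err / (n - 2)),
             time = (ss_time / 1) / (ss_wth_err / (n - 2)),
             int = (ss_int / 1) / (ss_wth_err / (n - 2))))
}

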