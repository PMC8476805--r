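# Independent brute-force oracles the implementation is checked against.
# These deliberately use naive loops / textbook formulas, not the package's
# own code paths.

# per-pixel double-loop threshold count
oracle_count_at_threshold <- function(patch, th, strict = FALSE) {
  count <- 0L
  for (i in seq_len(nrow(patch)))
    for (j in seq_len(ncol(patch)))
      count <- count + if (strict) patch[i, j] > th else patch[i, j] >= th
  count
}

# two-pass mean and (n-1)-denominator SD
oracle_mean_sd <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  list(mean = m, sd = sqrt(sum((x - m)^2) / (n - 1)))
}

# one-way ANOVA from the direct sum-of-squares decomposition
oracle_anova <- function(value, group) {
  group <- as.factor(group)
  grand <- mean(value)
  ssb <- 0; ssw <- 0
  for (g in levels(group)) {
    v <- value[group == g]
    ssb <- ssb + length(v) * (mean(v) - grand)^2
    ssw <- ssw + sum((v - mean(v))^2)
  }
  df1 <- nlevels(group) - 1L
  df2 <- length(value) - nlevels(group)
  Fv <- (ssb / df1) / (ssw / df2)
  list(F = Fv, p = stats::pf(Fv, df1, df2, lower.tail = FALSE),
       ss_between = ssb, ss_within = ssw)
}

# Monte-Carlo null distribution of the Dunnett max-|t| statistic for a
# balanced one-way layout: k comparison groups plus control, n per group
oracle_dunnett_maxt <- function(k, n, n_draws = 2e5, seed = 1) {
  withr::with_seed(seed, {
    groups <- k + 1L
    x <- array(stats::rnorm(n_draws * groups * n), c(n_draws, groups, n))
    m <- apply(x, c(1, 2), mean)
    v <- apply(x, c(1, 2), stats::var)
    df <- groups * (n - 1L)
    s2 <- rowSums(v * (n - 1L)) / df
    tstat <- (m[, -1L, drop = FALSE] - m[, 1L]) / sqrt(s2 * 2 / n)
    apply(abs(tstat), 1L, max)
  })
}

# mid-band column of a rendered scene's upper wall, in patch coordinates
scene_true_band_px <- function(scene) scene$walls$band_px
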