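#' A per-subject physiological time-course table
#'
#' Long-format container for one endpoint measured on a schedule of hours:
#' one row per subject and hour. The statistical policy of the package —
#' mean +/- SD summaries, one-way ANOVA across hours, Dunnett many-to-one
#' comparisons against the baseline hour — consumes this table.
#'
#' @param df data.frame with columns `subject_id`, `hour`, `value`.
#' @param variable endpoint tag (e.g. `"sdc1"`).
#' @param units measurement units.
#' @return A `time_course_table` (data.frame subclass with attributes
#'   `variable` and `units`).
#' @export
time_course_table <- function(df, variable = "value", units = "") {
  stopifnot(is.data.frame(df),
            all(c("subject_id", "hour", "value") %in% names(df)))
  if (!is.numeric(df$hour) || !is.numeric(df$value))
    stop("`hour` and `value` must be numeric")
  structure(df, variable = variable, units = units,
            class = c("time_course_table", "data.frame"))
}

#' Per-hour mean, SD and n of a time-course table
#'
#' SD uses the n-1 denominator, the convention behind "mean +/- SD"
#' reporting. Groups with a single value get `sd = NA` and are flagged.
#'
#' @param table a [time_course_table] (or data.frame with `hour`, `value`).
#' @return data.frame: `hour`, `n`, `mean`, `sd`, `sd_estimable`.
#' @export
summarize_time_course <- function(table) {
  if (nrow(table) == 0L) stop("empty table: nothing to summarize")
  out <- do.call(rbind, lapply(split(table$value, table$hour), function(v)
    data.frame(n = length(v), mean = mean(v),
               sd = if (length(v) >= 2L) stats::sd(v) else NA_real_,
               sd_estimable = length(v) >= 2L)))
  out <- cbind(hour = as.numeric(rownames(out)), out)
  rownames(out) <- NULL
  out[order(out$hour), , drop = FALSE]
}

#' Classical one-way fixed-effects ANOVA of value by hour
#'
#' A wrapper over `stats::lm`/`stats::anova` with explicit degenerate
#' handling: when every observation is identical, the between-group variance
#' is zero and the test carries no evidence against the null — the result is
#' `F = 0, p = 1`, flagged degenerate (the raw 0/0 ratio is undefined). When
#' groups differ but all residuals are zero, `F = Inf, p = 0`.
#'
#' @param table a [time_course_table]; every hour must have >= 2 values.
#' @return A list: `F`, `p`, `df` (c(between, within)), `ss_between`,
#'   `ss_within`, `degenerate`.
#' @export
one_way_anova <- function(table) {
  g <- factor(table$hour)
  if (nlevels(g) < 2L) stop("need at least 2 hour groups")
  n_per <- table(g)
  if (any(n_per < 2L))
    stop("every hour group needs >= 2 values for variance estimation (",
         paste(names(n_per)[n_per < 2L], collapse = ", "), " h too small)")
  df1 <- nlevels(g) - 1L
  df2 <- length(table$value) - nlevels(g)
  gm <- tapply(table$value, g, mean)
  ssb <- sum(n_per * (gm - mean(table$value))^2)
  ssw <- sum((n_per - 1L) * tapply(table$value, g, stats::var))
  if (ssb == 0 && ssw == 0) {
    return(list(F = 0, p = 1, df = c(df1, df2),
                ss_between = 0, ss_within = 0, degenerate = TRUE))
  }
  if (ssw == 0) {  # groups differ with zero residual variance
    return(list(F = Inf, p = 0, df = c(df1, df2),
                ss_between = ssb, ss_within = 0, degenerate = FALSE))
  }
  an <- stats::anova(stats::lm(value ~ g, data = data.frame(value = table$value, g = g)))
  list(F = an$`F value`[1L], p = an$`Pr(>F)`[1L], df = c(df1, df2),
       ss_between = an$`Sum Sq`[1L], ss_within = an$`Sum Sq`[2L],
       degenerate = FALSE)
}

#' Dunnett many-to-one comparisons against the baseline hour
#'
#' Two-sided comparisons of every hour's mean against the control hour, with
#' familywise error control through the joint multivariate-t distribution of
#' the comparison statistics: with pooled within-group variance `s^2` on
#' `N - K` degrees of freedom and group sizes `n_i`, the statistics
#' `t_i = (m_i - m_0) / (s * sqrt(1/n_i + 1/n_0))` are jointly t-distributed
#' with correlation `rho_ij = lambda_i * lambda_j`,
#' `lambda_i = sqrt(n_i / (n_i + n_0))` (0.5 for balanced designs). The
#' adjusted p-value of comparison `i` is
#' `1 - P(max_j |T_j| <= |t_i|)`, evaluated with `mvtnorm::pmvt`
#' (quasi-Monte-Carlo with a fixed internal seed, absolute error <= 1e-3, so
#' results are deterministic). With a single comparison this reduces exactly
#' to the two-sided two-sample t-test on the pooled variance.
#'
#' @param table a [time_course_table].
#' @param control_hour the reference group (default 0 h).
#' @param alpha familywise significance level (default 0.05).
#' @return A `dunnett_result`: data.frame `comparisons` (`hour`, `n`, `mean`,
#'   `mean_diff`, `t`, `p_unadjusted`, `p_adjusted`, `significant`), plus
#'   `anova` (the [one_way_anova] of the table), `control_hour`, `control_n`,
#'   `control_mean`, `alpha`, `df`.
#' @export
dunnett_vs_control <- function(table, control_hour = 0, alpha = 0.05) {
  g <- factor(table$hour)
  if (!any(table$hour == control_hour))
    stop("control group (", control_hour, " h) is missing from the table")
  an <- one_way_anova(table)
  hours <- sort(unique(table$hour))
  others <- hours[hours != control_hour]
  k <- length(others)
  n <- tapply(table$value, g, length)
  m <- tapply(table$value, g, mean)
  v <- tapply(table$value, g, stats::var)
  df <- sum(n) - length(hours)
  s2 <- sum((n - 1) * v) / df
  key <- as.character(control_hour)
  n0 <- n[[key]]; m0 <- m[[key]]
  ok <- as.character(others)
  se <- sqrt(s2 * (1 / n[ok] + 1 / n0))
  tstat <- (m[ok] - m0) / se
  lambda <- sqrt(n[ok] / (n[ok] + n0))
  corr <- outer(lambda, lambda)
  diag(corr) <- 1
  p_unadj <- 2 * stats::pt(-abs(tstat), df)
  p_adj <- vapply(abs(tstat), function(q) {
    if (!is.finite(q)) return(0)
    if (k == 1L) return(2 * stats::pt(-q, df))
    pr <- withr::with_seed(290873L,
      mvtnorm::pmvt(lower = rep(-q, k), upper = rep(q, k), df = df,
                    corr = corr, type = "shifted",
                    algorithm = mvtnorm::GenzBretz(abseps = 1e-3,
                                                   maxpts = 25000L)))
    min(max(1 - as.numeric(pr), 0), 1)
  }, numeric(1L))
  p_adj <- pmax(p_adj, p_unadj)  # adjustment can only increase p
  comparisons <- data.frame(hour = others,
                            n = as.vector(n[ok]),
                            mean = as.vector(m[ok]),
                            mean_diff = as.vector(m[ok] - m0),
                            t = as.vector(tstat),
                            p_unadjusted = as.vector(p_unadj),
                            p_adjusted = as.vector(p_adj),
                            significant = as.vector(p_adj < alpha))
  structure(list(comparisons = comparisons, anova = an,
                 control_hour = control_hour, control_n = n0,
                 control_mean = m0, alpha = alpha, df = df),
            class = "dunnett_result")
}

#' @export
print.dunnett_result <- function(x, ...) {
  cat(sprintf("Dunnett comparisons vs %g h (alpha = %g); ANOVA F = %.3f, p = %.4g\n",
              x$control_hour, x$alpha, x$anova$F, x$anova$p))
  stars <- ifelse(x$comparisons$p_adjusted < 0.01, "**",
                  ifelse(x$comparisons$p_adjusted < 0.05, "*", ""))
  df <- cbind(x$comparisons, ` ` = stars)
  print(df, row.names = FALSE, digits = 4)
  invisible(x)
}
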