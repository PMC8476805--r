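#' Default cohort parameters for the emulated study endpoints
#'
#' Per-variable defaults for [cohort_spec()]: the observation schedule (hours
#' after endotoxin challenge) and per-hour means and SDs. Where the study
#' protocol this package emulates prints numerical values they are used
#' verbatim — plasma syndecan-1 1.85 +/- 0.48 ng/mL at baseline rising to
#' 3.83 +/- 1.09 ng/mL at 24 h (n = 3), arteriolar thickness index
#' 1.28 +/- 0.27 vs 1.79 +/- 0.62 and venular 1.05 +/- 0.39 vs 1.51 +/- 0.56
#' (n = 21) — with recovery to baseline from 48 h on. Body weight and blood
#' pressure are reported there only graphically, so realistic BALB/c values
#' consistent with the described course are used: weight minimum at 48 h with
#' recovery by 168 h (n = 8), mean blood pressure minimum at 24 h with
#' recovery by 72 h (n = 5).
#'
#' @param variable one of `"sdc1"`, `"body_weight"`, `"blood_pressure"`,
#'   `"ti_arteriole"`, `"ti_venule"`.
#' @return A list with `schedule`, `group_means`, `group_sds`, `n_per_time`,
#'   `truncate_at_zero`, `units`.
#' @export
cohort_defaults <- function(variable = c("sdc1", "body_weight",
                                         "blood_pressure",
                                         "ti_arteriole", "ti_venule")) {
  variable <- match.arg(variable)
  switch(variable,
    sdc1 = list(
      schedule = c(0, 24, 48, 96),
      group_means = c(1.85, 3.83, 1.85, 1.85),
      group_sds = c(0.48, 1.09, 0.48, 0.48),
      n_per_time = 3L, truncate_at_zero = TRUE, units = "ng/mL"),
    body_weight = list(
      schedule = c(0, 24, 48, 72, 96, 120, 168, 216),
      group_means = c(22.5, 21.0, 20.2, 21.0, 21.8, 22.1, 22.5, 22.6),
      group_sds = rep(1.0, 8), n_per_time = 8L,
      truncate_at_zero = FALSE, units = "g"),
    blood_pressure = list(
      schedule = c(0, 24, 48, 72, 96),
      group_means = c(85, 65, 70, 82, 84),
      group_sds = rep(8, 5), n_per_time = 5L,
      truncate_at_zero = FALSE, units = "mmHg"),
    ti_arteriole = list(
      schedule = c(0, 24, 48, 72),
      group_means = c(1.28, 1.79, 1.28, 1.28),
      group_sds = c(0.27, 0.62, 0.27, 0.27),
      n_per_time = 21L, truncate_at_zero = TRUE, units = "um"),
    ti_venule = list(
      schedule = c(0, 24, 48, 72),
      group_means = c(1.05, 1.51, 1.05, 1.05),
      group_sds = c(0.39, 0.56, 0.39, 0.39),
      n_per_time = 21L, truncate_at_zero = TRUE, units = "um"))
}

#' Specification of a synthetic physiological time-course cohort
#'
#' @param variable endpoint name; defaults for schedule/means/SDs come from
#'   [cohort_defaults()] and any can be overridden.
#' @param schedule observation hours; must be a subset of the protocol grid
#'   0, 24, 48, 72, 96, 120, 168, 216 h.
#' @param group_means,group_sds one value per scheduled hour.
#' @param n_per_time independent draws per hour (>= 2 so SD is estimable).
#' @param truncate_at_zero if `TRUE`, draws are from the normal left-truncated
#'   at 0 (concentrations and thicknesses cannot be negative).
#' @param seed integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(variable = "sdc1",
                        schedule = NULL, group_means = NULL, group_sds = NULL,
                        n_per_time = NULL, truncate_at_zero = NULL,
                        seed = 1L) {
  def <- cohort_defaults(variable)
  if (is.null(schedule)) schedule <- def$schedule
  grid <- c(0, 24, 48, 72, 96, 120, 168, 216)
  if (!all(schedule %in% grid))
    stop("schedule hours must be a subset of the protocol grid {",
         paste(grid, collapse = ", "), "}")
  if (is.null(group_means))
    group_means <- def$group_means[match(schedule, def$schedule)]
  if (is.null(group_sds))
    group_sds <- def$group_sds[match(schedule, def$schedule)]
  if (anyNA(group_means) || anyNA(group_sds) ||
      length(group_means) != length(schedule) ||
      length(group_sds) != length(schedule))
    stop("a mean and SD must be supplied (or available as default) for every ",
         "scheduled hour")
  if (is.null(n_per_time)) n_per_time <- def$n_per_time
  if (n_per_time < 2L) stop("n_per_time must be >= 2 (SD must be estimable)")
  if (is.null(truncate_at_zero)) truncate_at_zero <- def$truncate_at_zero
  if (any(group_sds < 0)) stop("group_sds must be non-negative")
  structure(list(variable = variable, schedule = schedule,
                 group_means = group_means, group_sds = group_sds,
                 n_per_time = as.integer(n_per_time),
                 truncate_at_zero = truncate_at_zero,
                 units = def$units, seed = as.integer(seed)),
            class = "cohort_spec")
}

# normal draws, redrawn while negative (left truncation at 0)
.rnorm_trunc0 <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < 0)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Simulate a physiological time-course cohort
#'
#' Draws `n_per_time` independent subjects per scheduled hour from a normal
#' with the configured mean and SD (left-truncated at zero for non-negative
#' quantities).
#'
#' @param spec a [cohort_spec].
#' @return A [time_course_table].
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  df <- withr::with_seed(spec$seed, {
    do.call(rbind, lapply(seq_along(spec$schedule), function(i) {
      h <- spec$schedule[i]
      v <- if (spec$truncate_at_zero)
        .rnorm_trunc0(spec$n_per_time, spec$group_means[i], spec$group_sds[i])
      else
        stats::rnorm(spec$n_per_time, spec$group_means[i], spec$group_sds[i])
      data.frame(subject_id = sprintf("h%03d_s%02d", h, seq_len(spec$n_per_time)),
                 hour = h, value = v)
    }))
  })
  time_course_table(df, variable = spec$variable, units = spec$units)
}
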