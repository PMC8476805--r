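#' Configuration of an emulated end-to-end run
#'
#' Collects every tunable of the pipeline in one place, with defaults equal
#' to the protocol values where the protocol fixes them (threshold fraction
#' `F = 0.7`, pixel size 0.377 um/px, 15-s observation window, 30-min
#' permeability sampling up to 120 min, `alpha = 0.05`) and to the package's
#' documented choices elsewhere. Computation paths read every constant from
#' this object, never from hard-coded literals.
#'
#' @param seed master seed; every endpoint derives its own sub-seed from it.
#' @param pixel_size um per pixel.
#' @param F threshold fraction for the thickness index.
#' @param displacement_epsilon,rolling_fraction,match_radius leukocyte
#'   classification tunables, um / fraction / um.
#' @param alpha significance level.
#' @param window leukocyte observation window, s.
#' @param frame_rate track sampling rate, Hz.
#' @param centerline_speed free-flow reference speed, um/s.
#' @param leak_times permeability acquisition grid, min.
#' @param perm_leak_rate generator leak rate for the permeability emulation,
#'   gray levels/min (0: the no-hyperpermeability regime).
#' @param ti_hours,adhesion_hours,perm_hours endpoint schedules, h.
#' @param n_ti_per_group,n_adhesion_videos,n_perm_locations cohort sizes
#'   (TI measurements per vessel class and hour; videos per class and hour;
#'   time-lapse locations at each permeability hour).
#' @param always_posthoc run Dunnett comparisons even when the global ANOVA
#'   is not significant (default `FALSE`: post-hoc only after a significant
#'   ANOVA).
#' @param out_dir directory for CSV outputs and the run report; `NULL` keeps
#'   results in memory only.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L,
                       pixel_size = 0.377,
                       F = 0.7,
                       displacement_epsilon = 2,
                       rolling_fraction = 0.5,
                       match_radius = 5,
                       alpha = 0.05,
                       window = 15,
                       frame_rate = 2,
                       centerline_speed = 100,
                       leak_times = c(0, 30, 60, 90, 120),
                       perm_leak_rate = 0,
                       ti_hours = c(0, 24, 48, 72),
                       adhesion_hours = c(0, 24, 48),
                       perm_hours = c(0, 24),
                       n_ti_per_group = 21L,
                       n_adhesion_videos = 12L,
                       n_perm_locations = c(`0` = 9L, `24` = 18L),
                       always_posthoc = FALSE,
                       out_dir = NULL) {
  cfg <- list(seed = as.integer(seed), pixel_size = pixel_size, F = F,
              displacement_epsilon = displacement_epsilon,
              rolling_fraction = rolling_fraction,
              match_radius = match_radius, alpha = alpha, window = window,
              frame_rate = frame_rate, centerline_speed = centerline_speed,
              leak_times = leak_times, perm_leak_rate = perm_leak_rate,
              ti_hours = ti_hours, adhesion_hours = adhesion_hours,
              perm_hours = perm_hours,
              n_ti_per_group = as.integer(n_ti_per_group),
              n_adhesion_videos = as.integer(n_adhesion_videos),
              n_perm_locations = n_perm_locations,
              always_posthoc = always_posthoc, out_dir = out_dir)
  stopifnot(cfg$pixel_size > 0, cfg$F >= 0, cfg$F <= 1,
            cfg$alpha > 0, cfg$alpha < 1, cfg$window > 0)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @return `config_hash`: a short deterministic hash of every tunable
#'   (excluding output paths), recorded in run provenance.
#' @export
config_hash <- function(config) {
  stopifnot(inherits(config, "run_config"))
  rlang::hash(unclass(config)[setdiff(names(config), "out_dir")])
}

# deterministic sub-seed below 2^31 from (master seed, endpoint tag)
derive_seed <- function(seed, tag) {
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 131 + ch) %% 1000000007
  as.integer((h + as.numeric(seed) * 97003) %% 2147483647)
}

.gated_stats <- function(table, config) {
  an <- one_way_anova(table)
  dn <- if (an$p < config$alpha || config$always_posthoc)
    dunnett_vs_control(table, control_hour = 0, alpha = config$alpha)
  else NULL
  list(summary = summarize_time_course(table), anova = an, dunnett = dn,
       posthoc_run = !is.null(dn))
}

.emulate_ti <- function(config) {
  rows <- list()
  for (cls in c("arteriole", "venule")) {
    def <- cohort_defaults(paste0("ti_", cls))
    for (i in seq_along(config$ti_hours)) {
      h <- config$ti_hours[i]
      mu <- def$group_means[match(h, def$schedule)]
      sdv <- def$group_sds[match(h, def$schedule)]
      if (is.na(mu)) stop("no TI generator parameters for hour ", h)
      sd0 <- derive_seed(config$seed, paste0("ti_", cls, "_", h))
      # truths floored at one pixel: the renderer cannot draw a sub-resolution
      # band, and a bandless wall ROI makes the relative threshold degenerate
      draws <- withr::with_seed(sd0, list(
        truth = pmax(.rnorm_trunc0(config$n_ti_per_group, mu, sdv),
                     config$pixel_size),
        diam = stats::runif(config$n_ti_per_group, 20, 50),
        seeds = sample.int(2^30, config$n_ti_per_group)))
      for (j in seq_len(config$n_ti_per_group)) {
        sc <- render_vessel_scene(scene_spec(
          vessel_diameter = draws$diam[j],
          gcx_thickness_true = draws$truth[j],
          pixel_size = config$pixel_size,
          seed = draws$seeds[j]))
        ti <- compute_ti(sc$frame, wall_roi(sc), F = config$F)
        rows[[length(rows) + 1L]] <- data.frame(
          vessel_class = cls, hour = h, measurement = j,
          true_thickness_um = draws$truth[j], ti_px = ti$ti_px,
          ti_um = ti$ti_um, threshold = ti$threshold_used,
          degenerate = ti$degenerate)
      }
    }
  }
  meas <- do.call(rbind, rows)
  stats <- lapply(stats::setNames(nm = c("arteriole", "venule")), function(cls) {
    d <- meas[meas$vessel_class == cls & !is.na(meas$ti_um), ]
    .gated_stats(time_course_table(
      data.frame(subject_id = paste0(d$hour, "_", d$measurement),
                 hour = d$hour, value = d$ti_um),
      variable = paste0("ti_", cls), units = "um"), config)
  })
  list(endpoint = "ti", measurements = meas,
       summary = summarize_vessels(meas), stats = stats)
}

# generator class-count means per hour: the venular interaction surge at
# 24 h with return by 48 h, flat arterioles (counts per observed segment)
.adhesion_count_means <- function(cls, hour) {
  if (cls == "venule")
    list(rolling = c(`0` = 4, `24` = 12, `48` = 5)[[as.character(hour)]],
         adhering = c(`0` = 2, `24` = 4, `48` = 2)[[as.character(hour)]])
  else
    list(rolling = 3, adhering = 1)
}

.emulate_adhesion <- function(config) {
  rows <- list()
  for (cls in c("arteriole", "venule")) {
    for (h in config$adhesion_hours) {
      sd0 <- derive_seed(config$seed, paste0("adhesion_", cls, "_", h))
      mu <- .adhesion_count_means(cls, h)
      draws <- withr::with_seed(sd0, list(
        n_rol = stats::rpois(config$n_adhesion_videos, mu$rolling),
        n_adh = stats::rpois(config$n_adhesion_videos, mu$adhering),
        diam = stats::runif(config$n_adhesion_videos, 20, 50),
        seeds = sample.int(2^30, config$n_adhesion_videos)))
      for (v in seq_len(config$n_adhesion_videos)) {
        cohort <- simulate_tracks(track_spec(
          n_adhering = draws$n_adh[v], n_rolling = draws$n_rol[v],
          n_flowing = 5L, window = config$window,
          frame_rate = config$frame_rate,
          centerline_speed = config$centerline_speed,
          rolling_speed_fraction = 0.2,
          vessel_diameter = draws$diam[v], seed = draws$seeds[v]))
        cc <- count_and_normalize(
          cohort, reference_speed = config$centerline_speed,
          params = classify_params(
            displacement_epsilon = config$displacement_epsilon,
            rolling_fraction = config$rolling_fraction,
            window = config$window),
          vessel = c(cohort$tracks[[1L]]$vessel %||%
                       list(diameter_um = draws$diam[v],
                            segment_length_um = 100),
                     list(vessel_class = cls)))
        rows[[length(rows) + 1L]] <- data.frame(
          vessel_class = cls, hour = h, video = v,
          n_adhering = cc$n_adhering, n_rolling = cc$n_rolling,
          n_flowing = cc$n_flowing,
          normalized_adhering = cc$normalized_adhering,
          normalized_rolling = cc$normalized_rolling,
          normalization = cc$normalization)
      }
    }
  }
  meas <- do.call(rbind, rows)
  stats <- lapply(stats::setNames(nm = c("arteriole", "venule")), function(cls) {
    d <- meas[meas$vessel_class == cls, ]
    lapply(stats::setNames(nm = c("normalized_rolling", "normalized_adhering")),
           function(col) .gated_stats(time_course_table(
             data.frame(subject_id = paste0(d$hour, "_", d$video),
                        hour = d$hour, value = d[[col]]),
             variable = col, units = "per 100 um"), config))
  })
  list(endpoint = "adhesion", measurements = meas, stats = stats)
}

.emulate_permeability <- function(config) {
  rows <- list(); tests <- list()
  for (h in config$perm_hours) {
    n_loc <- config$n_perm_locations[[as.character(h)]]
    if (is.null(n_loc)) n_loc <- config$n_perm_locations[[1L]]
    series_list <- lapply(seq_len(n_loc), function(l) {
      sp <- leak_spec(times = config$leak_times,
                      leak_rate = config$perm_leak_rate,
                      pixel_size = config$pixel_size,
                      seed = derive_seed(config$seed,
                                         paste0("perm_", h, "_", l)))
      permeability_index(simulate_leak_series(sp))
    })
    tests[[as.character(h)]] <- trend_test(series_list, alpha = config$alpha)
    for (l in seq_along(series_list)) {
      d <- as.data.frame(series_list[[l]])
      d <- cbind(hour = h, location = l, d)
      rows[[length(rows) + 1L]] <- d
    }
  }
  list(endpoint = "permeability", measurements = do.call(rbind, rows),
       trend_tests = tests)
}

.emulate_cohort <- function(config) {
  vars <- c("sdc1", "body_weight", "blood_pressure")
  tables <- lapply(stats::setNames(nm = vars), function(v)
    simulate_cohort(cohort_spec(v, seed = derive_seed(config$seed,
                                                      paste0("cohort_", v)))))
  stats <- lapply(tables, .gated_stats, config = config)
  list(endpoint = "cohort",
       measurements = do.call(rbind, lapply(vars, function(v)
         cbind(variable = v, as.data.frame(tables[[v]])))),
       tables = tables, stats = stats)
}

#' Run one endpoint of the emulated study
#'
#' Simulates the endpoint's inputs at the protocol schedule, quantifies them
#' with the package's measurement operations, and runs the group statistics
#' (ANOVA, with Dunnett post-hoc gated on ANOVA significance unless
#' `always_posthoc`). Deterministic given the config and its seed.
#'
#' @param config a [run_config].
#' @param endpoint one of `"ti"`, `"adhesion"`, `"permeability"`, `"cohort"`.
#' @return A report fragment: list with `endpoint`, a `measurements`
#'   data.frame, endpoint-specific statistics, and `provenance` (config
#'   hash, seed, package version). CSVs are written when `config$out_dir`
#'   is set.
#' @export
run_endpoint <- function(config,
                         endpoint = c("ti", "adhesion", "permeability",
                                      "cohort")) {
  stopifnot(inherits(config, "run_config"))
  if (length(endpoint) != 1L || !endpoint %in% c("ti", "adhesion",
                                                 "permeability", "cohort"))
    stop("unknown endpoint '", paste(endpoint, collapse = ","),
         "'; usage: endpoint must be one of ti, adhesion, permeability, cohort")
  frag <- switch(endpoint,
                 ti = .emulate_ti(config),
                 adhesion = .emulate_adhesion(config),
                 permeability = .emulate_permeability(config),
                 cohort = .emulate_cohort(config))
  frag$provenance <- list(config_hash = config_hash(config),
                          seed = config$seed,
                          package_version =
                            as.character(utils::packageVersion("glycovivo")))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(frag$measurements,
                     file.path(config$out_dir,
                               paste0(endpoint, "_measurements.csv")),
                     row.names = FALSE)
  }
  frag
}

#' Run the full emulated study end to end
#'
#' Simulates all four endpoints on the protocol schedule, quantifies and
#' tests each, and assembles a run report with provenance. With an output
#' directory set, per-endpoint measurement CSVs and a markdown summary
#' juxtaposing the emulation's group summaries with the generator parameters
#' are written; two runs with the same config produce byte-identical CSVs.
#'
#' @param config a [run_config].
#' @return A `run_report` list: `fragments` per endpoint, `provenance`.
#' @export
run_full_emulation <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  fragments <- lapply(
    stats::setNames(nm = c("cohort", "ti", "adhesion", "permeability")),
    function(e) run_endpoint(config, e))
  report <- structure(
    list(fragments = fragments,
         provenance = list(config_hash = config_hash(config),
                           seed = config$seed,
                           package_version =
                             as.character(utils::packageVersion("glycovivo")),
                           r_version = R.version.string)),
    class = "run_report")
  if (!is.null(config$out_dir))
    .write_report_md(report, config)
  report
}

.fmt_stats <- function(st, label) {
  out <- c(sprintf("### %s", label),
           "",
           sprintf("ANOVA: F = %.3f, p = %.4g%s", st$anova$F, st$anova$p,
                   if (st$anova$degenerate) " (degenerate)" else ""))
  if (st$posthoc_run) {
    cmp <- st$dunnett$comparisons
    out <- c(out, "", "| hour | mean diff | adjusted p | significant |",
             "|---|---|---|---|",
             sprintf("| %g | %.4g | %.4g | %s |", cmp$hour, cmp$mean_diff,
                     cmp$p_adjusted, ifelse(cmp$significant, "yes", "no")))
  } else {
    out <- c(out, "", "Post-hoc comparisons not run (ANOVA not significant).")
  }
  c(out, "")
}

.write_report_md <- function(report, config) {
  lines <- c("# Emulated study run report", "",
             sprintf("- config hash: %s", report$provenance$config_hash),
             sprintf("- seed: %d", report$provenance$seed),
             sprintf("- package version: %s",
                     report$provenance$package_version), "")
  co <- report$fragments$cohort
  for (v in names(co$stats)) {
    def <- cohort_defaults(v)
    lines <- c(lines, sprintf("## Cohort endpoint: %s", v), "",
               sprintf("Generator means (%s): %s", def$units,
                       paste(sprintf("%g h: %g", def$schedule,
                                     def$group_means), collapse = "; ")), "",
               .fmt_stats(co$stats[[v]], "group statistics"))
  }
  ti <- report$fragments$ti
  lines <- c(lines, "## Thickness index", "", "| class | hour | n | mean | sd |",
             "|---|---|---|---|---|",
             sprintf("| %s | %g | %d | %.3f | %.3f |", ti$summary$vessel_class,
                     ti$summary$hour, ti$summary$n, ti$summary$mean,
                     ti$summary$sd), "")
  for (cls in names(ti$stats))
    lines <- c(lines, .fmt_stats(ti$stats[[cls]], paste("TI", cls)))
  ad <- report$fragments$adhesion
  for (cls in names(ad$stats))
    for (col in names(ad$stats[[cls]]))
      lines <- c(lines, .fmt_stats(ad$stats[[cls]][[col]],
                                   paste("adhesion", cls, col)))
  pe <- report$fragments$permeability
  lines <- c(lines, "## Permeability trend tests", "")
  for (h in names(pe$trend_tests)) {
    tt <- pe$trend_tests[[h]]
    lines <- c(lines, sprintf("- %s h: F = %.3f, p = %.4g, significant: %s",
                              h, tt$statistic, tt$p_value,
                              if (tt$significant) "yes" else "no"))
  }
  writeLines(lines, file.path(config$out_dir, "report.md"))
}
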