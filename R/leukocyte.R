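#' Classification parameters for leukocyte-endothelium interaction
#'
#' Thresholds turning the observational definitions — adhering cells "do not
#' move" over the window, rolling cells move "more slowly than the blood" —
#' into reproducible rules:
#' \describe{
#'   \item{displacement_epsilon}{maximum displacement (um) over the window
#'     still counted as "not moving"; default 2 um, well below a leukocyte
#'     diameter.}
#'   \item{rolling_fraction}{a moving cell slower than this fraction of the
#'     free-flow reference speed is rolling; default 0.5.}
#'   \item{min_coverage}{minimum fraction of the window a track must span to
#'     be classified at all (guards against single-glimpse tracks).}
#'   \item{adhering_min_coverage}{an adhering call asserts immobility over
#'     the whole window, so it additionally requires the track to cover at
#'     least this fraction of it; default 0.9. Immobile tracks with less
#'     coverage are "indeterminate".}
#' }
#'
#' @param displacement_epsilon um; see above.
#' @param rolling_fraction fraction in (0, 1).
#' @param min_coverage fraction of the window.
#' @param adhering_min_coverage fraction of the window.
#' @param window observation window in seconds.
#' @return A parameter list.
#' @export
classify_params <- function(displacement_epsilon = 2,
                            rolling_fraction = 0.5,
                            min_coverage = 0.02,
                            adhering_min_coverage = 0.9,
                            window = 15) {
  stopifnot(displacement_epsilon >= 0,
            rolling_fraction > 0, rolling_fraction < 1,
            min_coverage >= 0, min_coverage <= 1,
            adhering_min_coverage >= 0, adhering_min_coverage <= 1,
            window > 0)
  list(displacement_epsilon = displacement_epsilon,
       rolling_fraction = rolling_fraction,
       min_coverage = min_coverage,
       adhering_min_coverage = adhering_min_coverage,
       window = window)
}

#' Classify one leukocyte track as adhering, rolling or flowing
#'
#' A track whose maximum pairwise displacement stays within
#' `displacement_epsilon` and that covers (nearly) the whole observation
#' window is adhering. Otherwise its mean along-axis speed — net displacement
#' projected on the vessel axis divided by the observed time span — is
#' compared with the free-flow reference: slower than
#' `rolling_fraction * reference_speed` is rolling, else flowing. Tracks too
#' short to judge are "indeterminate".
#'
#' @param track a [leukocyte_track].
#' @param reference_speed free-flow (centerline) speed in um/s, estimated per
#'   video, e.g. from fast tracer or freely flowing cells.
#' @param params a [classify_params()] list.
#' @return One of `"adhering"`, `"rolling"`, `"flowing"`, `"indeterminate"`.
#' @export
classify_track <- function(track, reference_speed,
                           params = classify_params()) {
  stopifnot(inherits(track, "leukocyte_track"), reference_speed > 0)
  s <- track$samples
  span <- max(s$t_s) - min(s$t_s)
  coverage <- span / params$window
  if (nrow(s) < 2L || coverage < params$min_coverage) return("indeterminate")
  d <- as.matrix(stats::dist(cbind(s$x_um, s$y_um)))
  if (max(d) <= params$displacement_epsilon) {
    return(if (coverage >= params$adhering_min_coverage) "adhering"
           else "indeterminate")
  }
  ax <- track$vessel$axis
  net <- c(s$x_um[nrow(s)] - s$x_um[1L], s$y_um[nrow(s)] - s$y_um[1L])
  speed <- abs(sum(net * ax)) / span
  if (speed < params$rolling_fraction * reference_speed) "rolling" else "flowing"
}

#' Classify, count and normalize a set of tracks from one vessel
#'
#' Counts adhering / rolling / flowing tracks and calibrates the interaction
#' counts to a reference vessel of 100 um length and 100 um diameter:
#' `normalized = raw * (100 / segment_length) * (100 / diameter)`. A
#' length-only calibration (`raw * 100 / segment_length`) is available via
#' `normalization`; the output records which was used.
#'
#' @param tracks list of [leukocyte_track] (or a `track_cohort`), all sharing
#'   the vessel geometry.
#' @param reference_speed free-flow speed in um/s.
#' @param params a [classify_params()] list.
#' @param vessel vessel geometry (`diameter_um`, `segment_length_um`,
#'   optional `vessel_class`); taken from the first track when `NULL`.
#' @param normalization `"length_and_diameter"` (default) or `"length_only"`.
#' @return A `classified_counts` list: raw `n_adhering`, `n_rolling`,
#'   `n_flowing`, `n_indeterminate`, normalized adhering/rolling counts,
#'   `normalization`, `vessel_class`, per-track `labels`.
#' @export
count_and_normalize <- function(tracks, reference_speed,
                                params = classify_params(),
                                vessel = NULL,
                                normalization = c("length_and_diameter",
                                                  "length_only")) {
  normalization <- match.arg(normalization)
  if (inherits(tracks, "track_cohort")) tracks <- tracks$tracks
  if (is.null(vessel) && length(tracks)) vessel <- tracks[[1L]]$vessel
  if (length(tracks)) {
    if (is.null(vessel$diameter_um) || is.null(vessel$segment_length_um) ||
        vessel$diameter_um <= 0 || vessel$segment_length_um <= 0)
      stop("vessel needs positive diameter_um and segment_length_um")
  }
  labels <- vapply(tracks, classify_track, character(1L),
                   reference_speed = reference_speed, params = params)
  n_adh <- sum(labels == "adhering")
  n_rol <- sum(labels == "rolling")
  factor_len <- if (length(tracks)) 100 / vessel$segment_length_um else 1
  factor_dia <- if (normalization == "length_and_diameter" && length(tracks))
    100 / vessel$diameter_um else 1
  structure(list(n_adhering = n_adh,
                 n_rolling = n_rol,
                 n_flowing = sum(labels == "flowing"),
                 n_indeterminate = sum(labels == "indeterminate"),
                 normalized_adhering = n_adh * factor_len * factor_dia,
                 normalized_rolling = n_rol * factor_len * factor_dia,
                 normalization = normalization,
                 vessel_class = vessel$vessel_class %||% NA_character_,
                 labels = labels),
            class = "classified_counts")
}

#' @export
print.classified_counts <- function(x, ...) {
  cat(sprintf(paste0("<classified_counts> adhering %d, rolling %d, flowing %d",
                     ", indeterminate %d\n  normalized (per 100 um, %s):",
                     " adhering %.2f, rolling %.2f\n"),
              x$n_adhering, x$n_rolling, x$n_flowing, x$n_indeterminate,
              x$normalization, x$normalized_adhering, x$normalized_rolling))
  invisible(x)
}

#' Dual-channel time-lag adherence test
#'
#' Emulates the two-color merge used to separate tightly adherent leukocytes
#' from transient (rolling/flowing) ones: the leukocyte channel is captured a
#' few seconds (default 8 s) after the glycocalyx channel, and a cell present
#' at (nearly) the same position in both captures — "yellow" in the merged
#' image — has stayed put for the lag and is scored tight-adherent.
#'
#' @param detections_t0 data.frame with columns `x_um`, `y_um`: cell
#'   positions in the first capture.
#' @param detections_t1 same, for the capture `lag` seconds later, in the
#'   same coordinate frame.
#' @param match_radius maximum distance (um) between the two captures for a
#'   cell to count as unmoved.
#' @param lag seconds between captures (metadata, recorded in the output).
#' @return data.frame: `detections_t0` plus a `status` column
#'   (`"tight_adherent"` / `"transient"`) and the matched distance
#'   `match_dist_um` (`NA` when no detection lies within `match_radius`).
#'   Attribute `lag_s` records the lag.
#' @export
dual_stain_adherence <- function(detections_t0, detections_t1,
                                 match_radius = 5, lag = 8) {
  stopifnot(match_radius > 0, lag > 0)
  n0 <- nrow(detections_t0)
  out <- detections_t0
  if (is.null(out)) out <- data.frame(x_um = numeric(0), y_um = numeric(0))
  out$status <- rep("transient", nrow(out))
  out$match_dist_um <- rep(NA_real_, nrow(out))
  if (nrow(out) > 0L && !is.null(detections_t1) && nrow(detections_t1) > 0L) {
    for (i in seq_len(nrow(out))) {
      d <- sqrt((detections_t1$x_um - out$x_um[i])^2 +
                (detections_t1$y_um - out$y_um[i])^2)
      if (min(d) <= match_radius) {
        out$status[i] <- "tight_adherent"
        out$match_dist_um[i] <- min(d)
      }
    }
  }
  attr(out, "lag_s") <- lag
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
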