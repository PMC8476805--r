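#' Specification of a synthetic leukocyte track cohort
#'
#' Describes tracks of three kinetic classes over one observation window in a
#' straight vessel segment, with the vessel axis along +x and lateral (y)
#' positions inside the vessel:
#' \describe{
#'   \item{adhering}{stationary over the whole window up to bounded jitter.}
#'   \item{rolling}{advancing at `rolling_speed_fraction * centerline_speed`.}
#'   \item{flowing}{advancing at the free-flow `centerline_speed`.}
#' }
#' Positional jitter is uniform on `[-jitter_sd, jitter_sd]` per coordinate,
#' so an adhering track's displacement between any two samples is hard-bounded
#' by `2 * sqrt(2) * jitter_sd`. Tracks faster than the segment allows enter
#' at a random time and are observed only while inside the segment, as real
#' cells transit the field of view.
#'
#' @param n_adhering,n_rolling,n_flowing class counts.
#' @param window observation window in seconds (default 15, the standard
#'   intravital recording length).
#' @param frame_rate sampling rate in Hz.
#' @param centerline_speed free-flow reference speed in um/s.
#' @param rolling_speed_fraction rolling speed as a fraction of
#'   `centerline_speed`, in (0, 1).
#' @param jitter_sd half-width of the uniform positional jitter in um.
#' @param segment_length observed vessel segment length in um.
#' @param vessel_diameter vessel diameter in um.
#' @param seed integer seed.
#' @return A `track_spec` list.
#' @export
track_spec <- function(n_adhering = 3L, n_rolling = 3L, n_flowing = 3L,
                       window = 15, frame_rate = 2, centerline_speed = 100,
                       rolling_speed_fraction = 0.2, jitter_sd = 0.5,
                       segment_length = 100, vessel_diameter = 30,
                       seed = 1L) {
  stopifnot(n_adhering >= 0, n_rolling >= 0, n_flowing >= 0,
            window > 0, frame_rate > 0,
            rolling_speed_fraction > 0, rolling_speed_fraction < 1,
            jitter_sd >= 0, segment_length > 0, vessel_diameter > 0)
  structure(list(n_adhering = as.integer(n_adhering),
                 n_rolling = as.integer(n_rolling),
                 n_flowing = as.integer(n_flowing),
                 window = window, frame_rate = frame_rate,
                 centerline_speed = centerline_speed,
                 rolling_speed_fraction = rolling_speed_fraction,
                 jitter_sd = jitter_sd,
                 segment_length = segment_length,
                 vessel_diameter = vessel_diameter,
                 seed = as.integer(seed)),
            class = "track_spec")
}

#' A single leukocyte track
#'
#' @param track_id identifier.
#' @param samples data.frame with columns `t_s`, `x_um`, `y_um` and strictly
#'   increasing timestamps; at least two samples.
#' @param vessel list with `diameter_um`, `segment_length_um`, `axis`
#'   (unit vector, flow direction) and optionally `vessel_class`.
#' @param window observation window length in seconds the track belongs to.
#' @return A `leukocyte_track` object.
#' @export
leukocyte_track <- function(track_id, samples, vessel, window = 15) {
  stopifnot(is.data.frame(samples),
            all(c("t_s", "x_um", "y_um") %in% names(samples)))
  if (nrow(samples) < 2L) stop("a track needs at least 2 samples")
  if (any(diff(samples$t_s) <= 0)) stop("timestamps must be strictly increasing")
  if (max(samples$t_s) - min(samples$t_s) > window + 1e-9)
    stop("track samples span more than the observation window")
  ax <- vessel$axis
  if (is.null(ax)) ax <- c(1, 0)
  vessel$axis <- ax / sqrt(sum(ax^2))
  structure(list(track_id = track_id,
                 samples = samples[order(samples$t_s), , drop = FALSE],
                 vessel = vessel, window = window),
            class = "leukocyte_track")
}

# one moving track: enters at x = 0 (or a random start if the whole window
# fits in the segment) and is sampled on the acquisition grid while inside
.moving_track <- function(id, speed, spec, grid, vessel) {
  L <- spec$segment_length
  transit <- L / speed
  if (transit >= spec$window) {
    x0 <- stats::runif(1, 0, L - speed * spec$window)
    t_in <- grid
    x <- x0 + speed * grid
  } else {
    if (transit < 1 / spec$frame_rate)
      stop("segment too short: a cell at ", speed,
           " um/s crosses it between two samples at ", spec$frame_rate, " Hz")
    repeat {
      t0 <- stats::runif(1, 0, spec$window - transit)
      t_in <- grid[grid >= t0 & grid <= t0 + transit]
      if (length(t_in) >= 2L) break
    }
    x <- speed * (t_in - t_in[1L]) + stats::runif(1, 0, max(0, L - speed * (max(t_in) - t_in[1L])))
  }
  y0 <- stats::runif(1, -spec$vessel_diameter / 2, spec$vessel_diameter / 2)
  n <- length(t_in)
  jx <- stats::runif(n, -spec$jitter_sd, spec$jitter_sd)
  jy <- stats::runif(n, -spec$jitter_sd, spec$jitter_sd)
  leukocyte_track(id,
                  data.frame(t_s = t_in, x_um = x + jx, y_um = y0 + jy),
                  vessel, window = spec$window)
}

#' Simulate leukocyte tracks of known kinetic class
#'
#' @param spec a [track_spec].
#' @return A list of class `track_cohort` with elements `tracks` (list of
#'   [leukocyte_track]) and `labels` (character vector of true classes,
#'   aligned with `tracks`), plus the `spec`.
#' @export
simulate_tracks <- function(spec) {
  stopifnot(inherits(spec, "track_spec"))
  vessel <- list(diameter_um = spec$vessel_diameter,
                 segment_length_um = spec$segment_length,
                 axis = c(1, 0))
  grid <- seq(0, spec$window, by = 1 / spec$frame_rate)
  out <- withr::with_seed(spec$seed, {
    tracks <- list(); labels <- character(0); id <- 0L
    for (i in seq_len(spec$n_adhering)) {
      id <- id + 1L
      x0 <- stats::runif(1, 0, spec$segment_length)
      y0 <- stats::runif(1, -spec$vessel_diameter / 2, spec$vessel_diameter / 2)
      n <- length(grid)
      tracks[[id]] <- leukocyte_track(
        sprintf("trk%03d", id),
        data.frame(t_s = grid,
                   x_um = x0 + stats::runif(n, -spec$jitter_sd, spec$jitter_sd),
                   y_um = y0 + stats::runif(n, -spec$jitter_sd, spec$jitter_sd)),
        vessel, window = spec$window)
      labels[id] <- "adhering"
    }
    for (i in seq_len(spec$n_rolling)) {
      id <- id + 1L
      tracks[[id]] <- .moving_track(
        sprintf("trk%03d", id),
        spec$rolling_speed_fraction * spec$centerline_speed, spec, grid, vessel)
      labels[id] <- "rolling"
    }
    for (i in seq_len(spec$n_flowing)) {
      id <- id + 1L
      tracks[[id]] <- .moving_track(sprintf("trk%03d", id),
                                    spec$centerline_speed, spec, grid, vessel)
      labels[id] <- "flowing"
    }
    list(tracks = tracks, labels = labels)
  })
  structure(c(out, list(spec = spec)), class = "track_cohort")
}

#' Flatten tracks to a long table / write or read the track CSV
#'
#' The on-disk exchange format is a CSV with columns
#' `track_id, t_s, x_um, y_um`.
#'
#' @param tracks a `track_cohort` or plain list of [leukocyte_track].
#' @return `tracks_to_df`: a data.frame in the exchange layout.
#' @export
tracks_to_df <- function(tracks) {
  if (inherits(tracks, "track_cohort")) tracks <- tracks$tracks
  do.call(rbind, lapply(tracks, function(tr)
    cbind(track_id = tr$track_id, tr$samples)))
}

#' @rdname tracks_to_df
#' @param path CSV path.
#' @export
write_tracks_csv <- function(tracks, path) {
  utils::write.csv(tracks_to_df(tracks), path, row.names = FALSE)
  invisible(path)
}

#' @rdname tracks_to_df
#' @param vessel vessel geometry list (`diameter_um`, `segment_length_um`,
#'   optional `axis`) attached to every track read back.
#' @param window observation window in seconds.
#' @export
read_tracks_csv <- function(path, vessel, window = 15) {
  df <- utils::read.csv(path)
  lapply(split(df, df$track_id), function(d)
    leukocyte_track(d$track_id[1L],
                    d[, c("t_s", "x_um", "y_um")], vessel, window = window))
}
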