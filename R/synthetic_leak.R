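#' Specification of a synthetic dye-leakage time-lapse
#'
#' Emulates the interstitial field of view after intravenous injection of a
#' fluorescent dextran tracer: a time-lapse of frames whose interstitial
#' intensity rises linearly with a controllable leak rate, observed through
#' square ROIs adjacent to the vessel. The expected ROI mean at time `t`
#' minutes is `baseline_intensity + leak_rate * t`.
#'
#' @param times acquisition times in minutes; non-negative, strictly
#'   increasing, must include 0. Default is the 30-min protocol grid
#'   0, 30, 60, 90, 120.
#' @param leak_rate interstitial intensity gain in gray levels per minute
#'   (>= 0).
#' @param baseline_intensity interstitial gray level at time 0.
#' @param noise_sd per-pixel Gaussian noise SD in gray levels.
#' @param n_rois number of square ROIs (default 3, the per-location protocol).
#' @param roi_size ROI edge length in um (default 30).
#' @param pixel_size um per pixel.
#' @param image_shape optional c(rows, cols); by default just large enough to
#'   hold the ROIs side by side with a 10-px margin.
#' @param seed integer seed.
#' @return A `leak_spec` list.
#' @export
leak_spec <- function(times = c(0, 30, 60, 90, 120),
                      leak_rate = 0.5,
                      baseline_intensity = 30,
                      noise_sd = 5,
                      n_rois = 3L,
                      roi_size = 30,
                      pixel_size = 0.377,
                      image_shape = NULL,
                      seed = 1L) {
  if (any(times < 0) || any(diff(times) <= 0) || times[1L] != 0)
    stop("`times` must be non-negative, strictly increasing, and include 0")
  stopifnot(leak_rate >= 0, noise_sd >= 0, n_rois >= 1, roi_size > 0,
            pixel_size > 0)
  roi_px <- max(1L, round(roi_size / pixel_size))
  margin <- 10L
  if (is.null(image_shape))
    image_shape <- c(roi_px + 2L * margin,
                     n_rois * roi_px + (n_rois + 1L) * margin)
  structure(list(times = times, leak_rate = leak_rate,
                 baseline_intensity = baseline_intensity,
                 noise_sd = noise_sd, n_rois = as.integer(n_rois),
                 roi_size = roi_size, roi_px = as.integer(roi_px),
                 margin = margin, pixel_size = pixel_size,
                 image_shape = as.integer(image_shape),
                 seed = as.integer(seed)),
            class = "leak_spec")
}

#' Simulate a leakage time-lapse series
#'
#' @param spec a [leak_spec].
#' @return A `timelapse_series`: list with `frames` (list of
#'   `list(t_min, frame)` in time order), `rois` (list of [roi_square]),
#'   `pixel_size`, `true_leak_rate` and the `spec`.
#' @export
simulate_leak_series <- function(spec) {
  stopifnot(inherits(spec, "leak_spec"))
  nr <- spec$image_shape[1L]; nc <- spec$image_shape[2L]
  rois <- lapply(seq_len(spec$n_rois), function(r)
    roi_square(x = spec$margin + (r - 1L) * (spec$roi_px + spec$margin) + 1L,
               y = spec$margin + 1L,
               size_px = spec$roi_px,
               roi_id = sprintf("roi%d", r)))
  frames <- withr::with_seed(spec$seed, lapply(spec$times, function(t) {
    v <- spec$baseline_intensity + spec$leak_rate * t
    img <- matrix(v, nr, nc)
    if (spec$noise_sd > 0)
      img <- img + matrix(stats::rnorm(nr * nc, sd = spec$noise_sd), nr, nc)
    list(t_min = t,
         frame = image_frame(pmin(pmax(round(img), 0), 255),
                             pixel_size = spec$pixel_size,
                             channel = "tmr_dextran"))
  }))
  structure(list(frames = frames, rois = rois, pixel_size = spec$pixel_size,
                 true_leak_rate = spec$leak_rate, spec = spec),
            class = "timelapse_series")
}
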