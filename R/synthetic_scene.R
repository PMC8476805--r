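#' Specification of a synthetic two-channel vessel scene
#'
#' Describes a straight microvessel rendered into an 8-bit frame: a dark
#' interstitial background, a brighter lumen, and a bright wall band on both
#' walls representing the lectin-stained glycocalyx of known true thickness.
#' The band is the bright structure, as in FITC-WGA staining.
#'
#' @param vessel_diameter vessel diameter in um. The imaging protocol selects
#'   vessels of 20-50 um; values outside that range are accepted with a
#'   warning.
#' @param vessel_axis_angle orientation of the vessel axis in degrees
#'   (0 = horizontal, measured from the +x axis toward +y/rows).
#' @param gcx_thickness_true true glycocalyx band thickness in um (>= 0).
#'   Internally discretized to `round(gcx_thickness_true / pixel_size)` whole
#'   pixels perpendicular to the axis.
#' @param lumen_intensity,band_intensity,background_intensity mean 8-bit gray
#'   levels of the three compartments. The band must be brighter than both
#'   lumen and background.
#' @param noise_sd standard deviation of additive Gaussian read-out noise in
#'   gray levels (>= 0); rendered values are rounded and clipped to \[0, 255\].
#' @param noise_model `"gaussian"` (default) or `"poisson"` (shot noise with
#'   the compartment mean as the Poisson rate, `noise_sd` ignored).
#' @param pixel_size um per pixel; default 0.377 (200 px = 75.4 um).
#' @param image_shape integer c(rows, cols) of the rendered frame.
#' @param seed integer seed; the same spec and seed give a bit-identical
#'   scene.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(vessel_diameter = 30,
                       vessel_axis_angle = 0,
                       gcx_thickness_true = 1.885,
                       lumen_intensity = 60,
                       band_intensity = 200,
                       background_intensity = 10,
                       noise_sd = 5,
                       noise_model = c("gaussian", "poisson"),
                       pixel_size = 0.377,
                       image_shape = c(256L, 256L),
                       seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(vessel_diameter > 0, gcx_thickness_true >= 0, noise_sd >= 0,
            pixel_size > 0, length(image_shape) == 2L, all(image_shape >= 8))
  if (band_intensity <= lumen_intensity || band_intensity <= background_intensity)
    stop("band_intensity must exceed both lumen_intensity and background_intensity ",
         "(the stained glycocalyx band is the bright structure)")
  for (v in c(lumen_intensity, band_intensity, background_intensity))
    if (v < 0 || v > 255) stop("intensities must be 8-bit gray levels in [0, 255]")
  if (vessel_diameter < 20 || vessel_diameter > 50)
    warning("vessel_diameter ", vessel_diameter,
            " um is outside the 20-50 um range the imaging protocol selects")
  structure(list(vessel_diameter = vessel_diameter,
                 vessel_axis_angle = vessel_axis_angle,
                 gcx_thickness_true = gcx_thickness_true,
                 lumen_intensity = lumen_intensity,
                 band_intensity = band_intensity,
                 background_intensity = background_intensity,
                 noise_sd = noise_sd,
                 noise_model = noise_model,
                 pixel_size = pixel_size,
                 image_shape = as.integer(image_shape),
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' Render a synthetic vessel scene with ground truth
#'
#' Renders the straight vessel described by a [scene_spec] and returns the
#' 8-bit frame together with the exact ground-truth band mask and the wall
#' geometry, so that thickness-index recovery can be tested against truth.
#'
#' Geometry: pixel centers sit at integer (x = column, y = row) coordinates;
#' the vessel axis passes through the image center. With `s` the signed
#' perpendicular distance of a pixel center from the axis, the lumen is
#' `|s| <= r`, each wall band is `r < |s| <= r + t` (with `r` the lumen
#' radius and `t` the band thickness, both in pixels), and everything else is
#' background. For an axis-aligned vessel the band is therefore exactly `t`
#' pixels thick on each wall; for oblique angles discretization is at most
#' one pixel.
#'
#' @param spec a [scene_spec].
#' @return A list of class `vessel_scene`:
#'   \describe{
#'     \item{frame}{the rendered [image_frame].}
#'     \item{band_mask}{logical matrix marking exactly the band pixels.}
#'     \item{walls}{list with `center` (x, y), `angle_deg`, `lumen_radius_px`,
#'       `band_px` (band thickness in whole pixels) and, per wall side (+1 /
#'       -1), the signed perpendicular offsets of the band.}
#'     \item{spec}{the input spec.}
#'   }
#' @export
render_vessel_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  nr <- spec$image_shape[1L]; nc <- spec$image_shape[2L]
  r_px <- (spec$vessel_diameter / 2) / spec$pixel_size
  t_px <- round(spec$gcx_thickness_true / spec$pixel_size)
  if (2 * (r_px + t_px) + 2 > min(nr, nc))
    stop("image too small to contain the vessel: needs at least ",
         ceiling(2 * (r_px + t_px) + 2), " px across, got ", min(nr, nc))
  cx <- (nc + 1) / 2; cy <- (nr + 1) / 2
  a <- spec$vessel_axis_angle * pi / 180
  # signed perpendicular coordinate of every pixel center
  s <- outer(seq_len(nr) - cy, seq_len(nc) - cx,
             function(dy, dx) dy * cos(a) - dx * sin(a))
  lumen <- abs(s) <= r_px
  band <- if (t_px >= 1L) abs(s) > r_px & abs(s) <= r_px + t_px
          else matrix(FALSE, nr, nc)
  base <- matrix(spec$background_intensity, nr, nc)
  base[lumen] <- spec$lumen_intensity
  base[band] <- spec$band_intensity
  img <- withr::with_seed(spec$seed, {
    if (spec$noise_model == "poisson") {
      matrix(stats::rpois(nr * nc, lambda = as.vector(base)), nr, nc)
    } else if (spec$noise_sd > 0) {
      base + matrix(stats::rnorm(nr * nc, sd = spec$noise_sd), nr, nc)
    } else base
  })
  img <- pmin(pmax(round(img), 0), 255)
  frame <- image_frame(img, pixel_size = spec$pixel_size, channel = "fitc_wga")
  walls <- list(center = c(x = cx, y = cy),
                angle_deg = spec$vessel_axis_angle,
                lumen_radius_px = r_px,
                band_px = t_px,
                band_offsets = list(`+1` = c(inner = r_px, outer = r_px + t_px),
                                    `-1` = c(inner = -r_px - t_px, outer = -r_px)))
  structure(list(frame = frame, band_mask = band, walls = walls, spec = spec),
            class = "vessel_scene")
}

#' Build the wall ROI of a rendered scene
#'
#' Constructs the oriented rectangular ROI (default 40 x 200 px) centered on
#' the glycocalyx band of one wall of a synthetic scene, its long axis along
#' the vessel axis — the placement a microscopist would choose by hand on a
#' real image.
#'
#' @param scene a `vessel_scene` from [render_vessel_scene()].
#' @param side `"upper"` (positive perpendicular offset, larger row index for
#'   a horizontal vessel) or `"lower"`.
#' @param width_px,length_px ROI dimensions in pixels.
#' @return An [oriented_roi].
#' @export
wall_roi <- function(scene, side = c("upper", "lower"),
                     width_px = 40L, length_px = 200L) {
  stopifnot(inherits(scene, "vessel_scene"))
  side <- match.arg(side)
  w <- scene$walls
  sgn <- if (side == "upper") 1 else -1
  s_center <- sgn * (w$lumen_radius_px + w$band_px / 2)
  a <- w$angle_deg * pi / 180
  axis <- c(cos(a), sin(a)); perp <- c(-sin(a), cos(a))
  s_anchor <- round(s_center) - width_px / 2
  anchor <- c(w$center[["x"]], w$center[["y"]]) -
    (length_px / 2) * axis + s_anchor * perp
  anchor <- round(anchor)  # snap to a pixel center so axis-aligned ROIs sample exactly
  oriented_roi(anchor_x = anchor[1L], anchor_y = anchor[2L],
               angle_deg = w$angle_deg,
               width_px = width_px, length_px = length_px,
               allow_nonstandard = TRUE)
}
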