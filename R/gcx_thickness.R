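#' An oriented rectangular ROI on a vessel wall
#'
#' The measurement region for the glycocalyx thickness index: a rectangle
#' whose long axis follows the direction of blood flow, placed over one side
#' of the vascular endothelium. The standard size is 40 x 200 px (at the
#' default calibration the 200-px axis spans 75.4 um); other sizes must be
#' requested explicitly via `allow_nonstandard`.
#'
#' @param anchor_x,anchor_y pixel coordinates (x = column, y = row) of the
#'   ROI corner at which both local axes start.
#' @param angle_deg direction of the long axis in degrees (0 = +x/columns,
#'   measured toward +y/rows).
#' @param width_px,length_px ROI dimensions across / along the axis.
#' @param allow_nonstandard set `TRUE` to permit dimensions other than
#'   40 x 200 px.
#' @return An `oriented_roi` list.
#' @export
oriented_roi <- function(anchor_x, anchor_y, angle_deg = 0,
                         width_px = 40L, length_px = 200L,
                         allow_nonstandard = FALSE) {
  if ((width_px != 40L || length_px != 200L) && !allow_nonstandard)
    stop("standard ROI is 40 x 200 px; pass allow_nonstandard = TRUE to override")
  stopifnot(width_px >= 1, length_px >= 1)
  structure(list(anchor = c(x = anchor_x, y = anchor_y),
                 angle_deg = angle_deg,
                 width_px = as.integer(width_px),
                 length_px = as.integer(length_px)),
            class = "oriented_roi")
}

#' Extract an oriented ROI patch from a frame
#'
#' Resamples the rectangle into a `width_px x length_px` matrix with the long
#' axis horizontal (patch columns run along the flow direction, rows across
#' it). Resampling is nearest-neighbour, so the 8-bit gray levels — and hence
#' the intensity histogram the threshold formula depends on — are preserved
#' exactly.
#'
#' @param frame an [image_frame].
#' @param roi an [oriented_roi]; must lie fully inside the frame.
#' @return Integer matrix `width_px x length_px`.
#' @export
extract_roi <- function(frame, roi) {
  stopifnot(inherits(frame, "image_frame"), inherits(roi, "oriented_roi"))
  a <- roi$angle_deg * pi / 180
  axis <- c(cos(a), sin(a)); perp <- c(-sin(a), cos(a))
  u <- seq_len(roi$length_px) - 1L   # along flow
  v <- seq_len(roi$width_px) - 1L    # across
  x <- roi$anchor[["x"]] + outer(v, u, function(vv, uu) uu * axis[1L] + vv * perp[1L])
  y <- roi$anchor[["y"]] + outer(v, u, function(vv, uu) uu * axis[2L] + vv * perp[2L])
  j <- floor(x + 0.5); i <- floor(y + 0.5)  # nearest pixel center
  if (min(i) < 1 || min(j) < 1 || max(i) > nrow(frame) || max(j) > ncol(frame))
    stop("ROI extends outside the image (rows ", min(i), "..", max(i),
         ", cols ", min(j), "..", max(j), ")")
  patch <- matrix(unclass(frame)[cbind(as.vector(i), as.vector(j))],
                  roi$width_px, roi$length_px)
  storage.mode(patch) <- "integer"
  patch
}

#' Histogram-derived binarization threshold of a wall ROI
#'
#' Computes `Th = F * (Imax - Imin) + Imin`, where `Imax` and `Imin` are the
#' brightest and darkest gray levels inside the patch and `F` is a fraction
#' chosen so that supra-threshold pixels capture the stained glycocalyx band
#' (default 0.7). The value is returned unrounded; optional rounding to an
#' integer gray level is available for software that thresholds on integers.
#'
#' @param patch integer matrix of gray levels (from [extract_roi()]).
#' @param F fraction in \[0, 1\].
#' @param round_threshold round `Th` to the nearest integer gray level.
#' @return The threshold as a single numeric value, with attributes `imax`,
#'   `imin` and `degenerate` (`TRUE` when the patch is flat, i.e.
#'   `Imax == Imin`).
#' @export
compute_threshold <- function(patch, F = 0.7, round_threshold = FALSE) {
  if (length(patch) == 0L) stop("empty patch")
  if (F < 0 || F > 1) stop("F must lie in [0, 1]")
  imax <- max(patch); imin <- min(patch)
  th <- F * (imax - imin) + imin
  if (round_threshold) th <- round(th)
  structure(th, imax = imax, imin = imin, degenerate = imax == imin)
}

#' Count glycocalyx pixels in a thresholded patch
#'
#' Binarizes the patch at `Th` and counts the supra-threshold class — after
#' the binarize-then-invert step of the imaging protocol these are the pixels
#' scored as glycocalyx. The comparison convention is `>=` by default
#' (`strict = TRUE` switches to `>`).
#'
#' @param patch integer matrix of gray levels.
#' @param th threshold (from [compute_threshold()], or any numeric).
#' @param strict count only pixels strictly above `th`.
#' @return Integer pixel count in `[0, length(patch)]`.
#' @export
binarize_and_count <- function(patch, th, strict = FALSE) {
  if (strict) sum(patch > as.numeric(th)) else sum(patch >= as.numeric(th))
}

#' Thickness index (TI) of the glycocalyx from one wall ROI
#'
#' Composes ROI extraction, histogram thresholding and pixel counting: the
#' count of supra-threshold pixels is divided by the ROI axis length (200 px)
#' to give the mean band thickness in pixels, then calibrated to micrometers
#' with the frame's pixel size. A flat ROI (`Imax == Imin`) carries no band
#' evidence: the result is flagged degenerate and the TI reported as `NA`
#' rather than the whole-ROI count.
#'
#' @param frame an [image_frame].
#' @param roi an [oriented_roi] over one side of the vascular endothelium.
#' @param F threshold fraction, see [compute_threshold()].
#' @param round_threshold,strict passed through to the threshold/count steps.
#' @return A `ti_result` list: `ti_um`, `ti_px`, `gcx_pixel_count`,
#'   `threshold_used`, `imax`, `imin`, `degenerate`, `roi`.
#' @export
compute_ti <- function(frame, roi, F = 0.7,
                       round_threshold = FALSE, strict = FALSE) {
  patch <- extract_roi(frame, roi)
  th <- compute_threshold(patch, F = F, round_threshold = round_threshold)
  degenerate <- attr(th, "degenerate")
  count <- binarize_and_count(patch, th, strict = strict)
  ti_px <- if (degenerate) NA_real_ else count / roi$length_px
  structure(list(ti_um = ti_px * pixel_size(frame),
                 ti_px = ti_px,
                 gcx_pixel_count = as.integer(count),
                 threshold_used = as.numeric(th),
                 imax = attr(th, "imax"), imin = attr(th, "imin"),
                 degenerate = degenerate,
                 roi = roi),
            class = "ti_result")
}

#' @export
print.ti_result <- function(x, ...) {
  if (x$degenerate)
    cat("<ti_result> degenerate (flat ROI, Imax == Imin ==", x$imax, "): TI is NA\n")
  else
    cat(sprintf("<ti_result> TI = %.3f um (%.3f px; %d px >= Th = %.2f)\n",
                x$ti_um, x$ti_px, x$gcx_pixel_count, x$threshold_used))
  invisible(x)
}

#' @export
as.data.frame.ti_result <- function(x, ...) {
  data.frame(Imax = x$imax, Imin = x$imin, Th = x$threshold_used,
             count = x$gcx_pixel_count, ti_px = x$ti_px, ti_um = x$ti_um,
             degenerate_flag = x$degenerate)
}

#' Summarize thickness-index measurements by vessel class and hour
#'
#' @param df data.frame with columns `ti_um`, `vessel_class`, `hour` (one row
#'   per measurement; degenerate measurements should be removed or carry
#'   `NA`).
#' @return data.frame with one row per (vessel_class, hour): `n`, `mean`,
#'   `sd` (n-1 denominator).
#' @export
summarize_vessels <- function(df) {
  stopifnot(all(c("ti_um", "vessel_class", "hour") %in% names(df)))
  df <- df[!is.na(df$ti_um), , drop = FALSE]
  if (nrow(df) == 0L) stop("no non-missing TI measurements to summarize")
  out <- do.call(rbind, lapply(
    split(df, list(df$vessel_class, df$hour), drop = TRUE),
    function(g) {
      if (nrow(g) < 2L)
        stop("group ", g$vessel_class[1L], "/", g$hour[1L],
             " h has fewer than 2 measurements")
      data.frame(vessel_class = g$vessel_class[1L], hour = g$hour[1L],
                 n = nrow(g), mean = mean(g$ti_um), sd = stats::sd(g$ti_um))
    }))
  out <- out[order(out$vessel_class, out$hour), , drop = FALSE]
  rownames(out) <- NULL
  out
}
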