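#' A square pixel-aligned ROI
#'
#' Interstitial measurement square for the permeability index; the protocol
#' places three 30 x 30 um squares adjacent to the vessel. Physical sizes are
#' converted to whole pixels with [roi_square_um()] (30 um at 0.377 um/px
#' rounds to 80 px).
#'
#' @param x,y pixel coordinates (column, row) of the top-left corner.
#' @param size_px edge length in pixels.
#' @param roi_id identifier.
#' @return A `roi_square` list.
#' @export
roi_square <- function(x, y, size_px, roi_id = "roi1") {
  stopifnot(x >= 1, y >= 1, size_px >= 1)
  structure(list(x = as.integer(x), y = as.integer(y),
                 size_px = as.integer(size_px), roi_id = roi_id),
            class = "roi_square")
}

#' @rdname roi_square
#' @param size_um edge length in um.
#' @param pixel_size um per pixel.
#' @export
roi_square_um <- function(x, y, size_um = 30, pixel_size = 0.377,
                          roi_id = "roi1") {
  roi_square(x, y, size_px = max(1L, round(size_um / pixel_size)),
             roi_id = roi_id)
}

#' Mean intensity inside a square ROI
#'
#' @param frame an [image_frame].
#' @param roi a [roi_square]; must lie fully inside the frame.
#' @return Arithmetic mean of the ROI's pixel gray levels.
#' @export
roi_mean_intensity <- function(frame, roi) {
  stopifnot(inherits(frame, "image_frame"), inherits(roi, "roi_square"))
  i <- roi$y:(roi$y + roi$size_px - 1L)
  j <- roi$x:(roi$x + roi$size_px - 1L)
  if (max(i) > nrow(frame) || max(j) > ncol(frame))
    stop("ROI extends outside the frame")
  mean(unclass(frame)[i, j])
}

#' Vascular permeability index of a time-lapse series
#'
#' For every ROI and frame, the mean interstitial intensity is computed and a
#' control value subtracted; the change relative to control is the
#' permeability index. By default the control is the same ROI's mean at the
#' baseline frame (t = 0), so the index at t = 0 is exactly zero and any
#' constant background shift common to all frames cancels. Alternatively a
#' separate background ROI can serve as control (`control = "roi"`), in which
#' case its mean in each frame is subtracted.
#'
#' @param series a `timelapse_series` (see [simulate_leak_series()]), or any
#'   list with `frames` = list of `list(t_min, frame)` and `rois` = list of
#'   [roi_square].
#' @param control `"baseline"` (default) or `"roi"`.
#' @param control_roi a [roi_square] used when `control = "roi"`.
#' @return A `permeability_index_series`: data.frame with columns `roi_id`,
#'   `t_min`, `mean_intensity`, `index`, plus attribute `aggregated` — the
#'   per-time mean index over ROIs.
#' @export
permeability_index <- function(series, control = c("baseline", "roi"),
                               control_roi = NULL) {
  control <- match.arg(control)
  times <- vapply(series$frames, function(f) f$t_min, numeric(1L))
  if (!any(times == 0)) stop("the baseline frame (t = 0) is missing")
  meas <- do.call(rbind, lapply(series$frames, function(f) {
    data.frame(roi_id = vapply(series$rois, function(r) r$roi_id, character(1L)),
               t_min = f$t_min,
               mean_intensity = vapply(series$rois, roi_mean_intensity,
                                       numeric(1L), frame = f$frame),
               control_mean = if (control == "roi")
                 roi_mean_intensity(f$frame, control_roi) else NA_real_)
  }))
  if (control == "baseline") {
    base <- meas[meas$t_min == 0, c("roi_id", "mean_intensity")]
    meas$index <- meas$mean_intensity -
      base$mean_intensity[match(meas$roi_id, base$roi_id)]
  } else {
    meas$index <- meas$mean_intensity - meas$control_mean
  }
  meas$control_mean <- NULL
  agg <- stats::aggregate(index ~ t_min, data = meas, FUN = mean)
  structure(meas, aggregated = agg,
            class = c("permeability_index_series", "data.frame"))
}

#' Test for a time trend in permeability indices
#'
#' Tests whether the interstitial index changes across the acquisition times.
#' Because every index of one ROI is measured against that same ROI's
#' baseline, indices within an ROI share the baseline frame's noise; the
#' default test therefore blocks on ROI — a randomized-block ANOVA of index
#' on time with ROI as the blocking factor, baseline time excluded (its
#' indices are identically zero and carry no information). This keeps the
#' nominal type-I error exact. A plain one-way ANOVA across times
#' (`method = "oneway"`, conservative under baseline subtraction) and a
#' linear regression slope test (`method = "slope"`) are available.
#'
#' @param index_series a `permeability_index_series`, or a list of them from
#'   several locations (ROIs are then distinguished per location).
#' @param alpha significance level (default 0.05).
#' @param method `"blocked"`, `"oneway"` or `"slope"`.
#' @return A `trend_test` list: `statistic` (F), `p_value`, `df`,
#'   `significant`, `effect_size` (partial eta squared for the time effect),
#'   `method`, `degenerate` (TRUE when all indices are identical and the test
#'   is skipped).
#' @export
trend_test <- function(index_series, alpha = 0.05,
                       method = c("blocked", "oneway", "slope")) {
  method <- match.arg(method)
  if (inherits(index_series, "permeability_index_series"))
    index_series <- list(index_series)
  df <- do.call(rbind, lapply(seq_along(index_series), function(k) {
    d <- as.data.frame(index_series[[k]])
    d$series_roi <- paste0("loc", k, "_", d$roi_id)
    d
  }))
  if (length(unique(df$t_min)) < 2L) stop("need at least 2 time points")
  if (length(unique(df$series_roi)) < 2L) stop("need at least 2 ROI series")
  post <- df[df$t_min > 0, , drop = FALSE]
  result <- function(Fstat, p, df1, df2, eta2, degenerate = FALSE)
    structure(list(statistic = Fstat, p_value = p, df = c(df1, df2),
                   significant = isTRUE(p < alpha), effect_size = eta2,
                   alpha = alpha, method = method, degenerate = degenerate),
              class = "trend_test")
  if (stats::var(post$index) == 0)
    return(result(0, 1, NA, NA, 0, degenerate = TRUE))
  if (method == "slope") {
    fit <- stats::lm(index ~ t_min, data = post)
    an <- stats::anova(fit)
    return(result(an$`F value`[1L], an$`Pr(>F)`[1L], an$Df[1L], an$Df[2L],
                  an$`Sum Sq`[1L] / sum(an$`Sum Sq`)))
  }
  fit <- if (method == "blocked")
    stats::lm(index ~ factor(series_roi) + factor(t_min), data = post)
  else
    stats::lm(index ~ factor(t_min), data = post)
  an <- stats::anova(fit)
  row <- which(rownames(an) == "factor(t_min)")
  eta2 <- an$`Sum Sq`[row] / (an$`Sum Sq`[row] + an$`Sum Sq`[nrow(an)])
  result(an$`F value`[row], an$`Pr(>F)`[row], an$Df[row], an$Df[nrow(an)], eta2)
}

#' @export
print.trend_test <- function(x, ...) {
  if (x$degenerate)
    cat("<trend_test> all indices identical; test skipped (F = 0, p = 1)\n")
  else
    cat(sprintf("<trend_test> %s: F(%g, %g) = %.3f, p = %.4g%s (alpha = %g)\n",
                x$method, x$df[1L], x$df[2L], x$statistic, x$p_value,
                if (x$significant) " *" else "", x$alpha))
  invisible(x)
}
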