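#' An 8-bit grayscale image frame with spatial calibration
#'
#' The unit all image operations in this package consume: a 2-D matrix of
#' integer gray levels in \[0, 255\] (rows are y, columns are x, pixel centers
#' at integer 1-based coordinates) together with the physical pixel size in
#' micrometers per pixel and a free-text channel tag (e.g. `"fitc_wga"`,
#' `"rhodamine"`, `"tmr_dextran"`).
#'
#' The default pixel size, 0.377 um/px, is the calibration of the imaging
#' setup the package emulates (a 200-px ROI axis corresponding to 75.4 um
#' under a 20x objective).
#'
#' @param pixels numeric or integer matrix of gray levels in \[0, 255\].
#'   Values are rounded to integers; fractional input is accepted for
#'   convenience but stored 8-bit.
#' @param pixel_size physical size of one pixel in micrometers (> 0).
#' @param channel character tag naming the fluorescence channel.
#' @return An object of class `image_frame`: the integer matrix with
#'   attributes `pixel_size` and `channel`.
#' @export
image_frame <- function(pixels, pixel_size = 0.377, channel = "gray") {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number")
  px <- round(pixels)
  if (anyNA(px) || min(px) < 0 || max(px) > 255)
    stop("pixel values must lie in [0, 255]")
  storage.mode(px) <- "integer"
  structure(px,
            pixel_size = pixel_size,
            channel = as.character(channel)[1L],
            class = c("image_frame", "matrix", "array"))
}

#' @export
print.image_frame <- function(x, ...) {
  cat(sprintf("<image_frame> %d x %d px, %.4g um/px, channel '%s', gray range [%d, %d]\n",
              nrow(x), ncol(x), attr(x, "pixel_size"), attr(x, "channel"),
              min(x), max(x)))
  invisible(x)
}

#' @rdname image_frame
#' @param x an `image_frame`.
#' @export
pixel_size <- function(x) attr(x, "pixel_size")

#' Read an 8-bit grayscale image from TIFF or PNG
#'
#' @param path file path; format is chosen by extension (`.tif`/`.tiff` or
#'   `.png`).
#' @param pixel_size calibration to attach, um/px.
#' @param channel channel tag to attach.
#' @return An [image_frame].
#' @export
read_frame <- function(path, pixel_size = 0.377, channel = "gray") {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: .", ext))
  if (length(dim(arr)) == 3L) arr <- arr[, , 1L]  # keep first channel
  image_frame(round(arr * 255), pixel_size = pixel_size, channel = channel)
}

#' Write an image frame as 8-bit grayscale TIFF or PNG
#'
#' @param frame an [image_frame].
#' @param path destination; `.tif`/`.tiff` or `.png`.
#' @return `path`, invisibly.
#' @export
write_frame <- function(frame, path) {
  stopifnot(inherits(frame, "image_frame"))
  m <- unclass(frame) / 255
  attributes(m) <- list(dim = dim(frame))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(m, path, bits.per.sample = 8L),
    png = png::writePNG(m, path),
    stop("unsupported image format: .", ext))
  invisible(path)
}
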