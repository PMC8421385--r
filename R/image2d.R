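#' 2-D image container
#'
#' The unit consumed by every image operation in the package: a matrix of
#' intensities in `[0, 1]` (rows = image y, columns = image x), an optional
#' physical pixel size, and an optional logical tissue mask of the same shape.
#' RGB arrays are converted to grayscale with Rec. 709 luma; the original
#' channels are retained for channel-selective operations such as
#' [percent_positive_area()].
#'
#' Angle convention used throughout: orientations are measured in radians,
#' counterclockwise from the +x (column) axis toward the +y (row) axis, and
#' reported on the axial interval `[0, pi)`.
#'
#' @param pixels numeric matrix in `[0, 1]`, or an h x w x 3 RGB array.
#' @param pixel_size optional physical size of one pixel (e.g. micrometers).
#' @param mask optional logical matrix, same shape; `TRUE` marks tissue.
#' @return an object of class `image2d` with elements `pixels`, `rgb`
#'   (or `NULL`), `pixel_size`, `mask`.
#' @export
image2d <- function(pixels, pixel_size = NULL, mask = NULL) {
  rgb <- NULL
  if (is.array(pixels) && length(dim(pixels)) == 3L) {
    if (dim(pixels)[3] < 3L) stopf("RGB array must have >= 3 channels")
    rgb <- pixels[, , 1:3, drop = FALSE]
    pixels <- 0.2126 * rgb[, , 1] + 0.7152 * rgb[, , 2] + 0.0722 * rgb[, , 3]
  }
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stopf("`pixels` must be a numeric matrix or RGB array")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) stopf("image must be non-empty")
  if (any(!is.finite(pixels))) stopf("image intensities must be finite")
  if (min(pixels) < 0 || max(pixels) > 1)
    stopf("image intensities must lie in [0, 1]")
  if (!is.null(mask)) {
    if (!is.matrix(mask) || !identical(dim(mask), dim(pixels)))
      stopf("`mask` must be a logical matrix with the same shape as `pixels`")
    mask <- mask > 0
  }
  if (!is.null(pixel_size)) assert_scalar_num(pixel_size, "pixel_size", lower = 1e-12)
  structure(list(pixels = pixels, rgb = rgb, pixel_size = pixel_size, mask = mask),
            class = "image2d")
}

#' @export
print.image2d <- function(x, ...) {
  cat(sprintf("<image2d> %d x %d px%s%s%s\n",
              nrow(x$pixels), ncol(x$pixels),
              if (!is.null(x$rgb)) ", RGB" else "",
              if (!is.null(x$pixel_size)) sprintf(", pixel size %g", x$pixel_size) else "",
              if (!is.null(x$mask)) sprintf(", mask (%.0f%% tissue)", 100 * mean(x$mask)) else ""))
  invisible(x)
}

is_image2d <- function(x) inherits(x, "image2d")

as_image2d <- function(x, ...) {
  if (is_image2d(x)) x else image2d(x, ...)
}

#' Read an image file into an [image2d()]
#'
#' Supports TIFF and PNG. Intensities are rescaled into `[0, 1]` if the file
#' stores integer levels.
#'
#' @param path file path ending in .tif/.tiff/.png.
#' @param pixel_size optional physical pixel size to attach.
#' @return an `image2d`.
#' @export
read_image <- function(path, pixel_size = NULL) {
  if (!file.exists(path)) stopf("image file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stopf("unsupported image format '.%s' (use TIFF or PNG)", ext))
  if (is.array(px) && length(dim(px)) == 3L && dim(px)[3] == 4L)
    px <- px[, , 1:3]  # drop alpha
  if (max(px) > 1) px <- px / max(px)
  image2d(px, pixel_size = pixel_size)
}

#' Write an [image2d()] (or matrix) to TIFF or PNG
#'
#' @param image an `image2d` or numeric matrix in `[0, 1]`.
#' @param path output path; format chosen from the extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  px <- if (is_image2d(image)) image$rgb %||% image$pixels else image
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(px, path),
    png = png::writePNG(px, path),
    stopf("unsupported image format '.%s' (use TIFF or PNG)", ext))
  invisible(path)
}
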