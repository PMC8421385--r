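#' Percent positive (fluorescent) area
#'
#' Counts the pixels above an intensity threshold inside the analysis mask
#' and reports them as a percentage of the mask area. The default Otsu
#' threshold is computed per image; a fixed threshold is available for batch
#' comparability and is recorded in the result either way. Channel
#' `"blue_dominant"` restricts the analysis to pixels where blue exceeds both
#' red and green (trichrome collagen-blue selection) and thresholds the blue
#' channel there.
#'
#' @param image an [image2d()]; RGB content is required for the R/G/B and
#'   blue-dominant channels.
#' @param channel `"gray"`, `"R"`, `"G"`, `"B"`, or `"blue_dominant"`.
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param fixed_value threshold in `[0, 1]`; required iff `method = "fixed"`.
#' @param mask optional logical matrix restricting the analysis (TRUE =
#'   analyze); defaults to the image's own mask, else the whole frame.
#' @return an `area_result`: `percent_positive`, `threshold_value`,
#'   `threshold_method`, `n_pixels_total`, `n_pixels_positive`, `channel`.
#' @export
percent_positive_area <- function(image,
                                  channel = c("gray", "R", "G", "B", "blue_dominant"),
                                  threshold_method = c("otsu", "fixed"),
                                  fixed_value = NULL, mask = NULL) {
  channel <- match.arg(channel)
  threshold_method <- match.arg(threshold_method)
  image <- as_image2d(image)
  if (threshold_method == "fixed") {
    if (is.null(fixed_value)) stopf("`fixed_value` is required with fixed thresholding")
    assert_scalar_num(fixed_value, "fixed_value", 0, 1)
  } else if (!is.null(fixed_value)) {
    stopf("`fixed_value` must only be given with threshold_method = \"fixed\"")
  }
  if (channel != "gray" && is.null(image$rgb))
    stopf("channel '%s' requires an RGB image", channel)
  ch <- switch(channel,
               gray = image$pixels,
               R = image$rgb[, , 1], G = image$rgb[, , 2], B = image$rgb[, , 3],
               blue_dominant = image$rgb[, , 3])
  mask <- mask %||% image$mask %||% matrix(TRUE, nrow(ch), ncol(ch))
  if (!identical(dim(mask), dim(ch))) stopf("mask shape does not match the image")
  mask <- mask > 0
  if (channel == "blue_dominant")
    mask <- mask & (image$rgb[, , 3] > image$rgb[, , 1]) & (image$rgb[, , 3] > image$rgb[, , 2])
  n_total <- sum(mask)
  if (n_total == 0L) stopf("empty analysis mask")
  vals <- ch[mask]
  thr <- if (threshold_method == "fixed") fixed_value else {
    if (max(vals) - min(vals) < 1e-12) {
      warnf("degenerate Otsu threshold: image is constant inside the mask")
      max(vals)  # nothing exceeds it; percent is 0 by definition
    } else EBImage::otsu(matrix(vals, ncol = 1), range = range(vals))
  }
  n_pos <- sum(vals > thr)
  structure(list(percent_positive = 100 * n_pos / n_total,
                 threshold_value = thr, threshold_method = threshold_method,
                 n_pixels_total = n_total, n_pixels_positive = n_pos,
                 channel = channel), class = "area_result")
}

#' @export
print.area_result <- function(x, ...) {
  cat(sprintf("<area_result> %.2f%% positive (%d / %d px, %s threshold %.4f, channel %s)\n",
              x$percent_positive, x$n_pixels_positive, x$n_pixels_total,
              x$threshold_method, x$threshold_value, x$channel))
  invisible(x)
}

#' Batch percent-positive-area report
#'
#' Runs [percent_positive_area()] over a vector of image files and returns
#' (optionally writes) a tidy report.
#'
#' @param paths image file paths (TIFF/PNG).
#' @param out_csv optional CSV output path.
#' @inheritParams percent_positive_area
#' @return data.frame with columns `file`, `channel`, `threshold_method`,
#'   `threshold`, `percent_positive`.
#' @export
percent_positive_batch <- function(paths, channel = "gray",
                                   threshold_method = "otsu",
                                   fixed_value = NULL, out_csv = NULL) {
  rows <- lapply(paths, function(p) {
    r <- percent_positive_area(read_image(p), channel = channel,
                               threshold_method = threshold_method,
                               fixed_value = fixed_value)
    data.frame(file = p, channel = r$channel,
               threshold_method = r$threshold_method,
               threshold = r$threshold_value,
               percent_positive = r$percent_positive)
  })
  out <- do.call(rbind, rows)
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}
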