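#' Generate a fluorescence-like image with known positive-area fraction
#'
#' `style = "binary"` sets an exact number of randomly chosen pixels to the
#' foreground level, so the true fraction equals the requested fraction to one
#' pixel quantum. `style = "blobs"` composes soft-edged disks until the target
#' coverage is reached, giving a graded image whose true fraction is the exact
#' count of pixels above the 0.5 intensity midpoint.
#'
#' @param size `c(rows, cols)`.
#' @param positive_fraction target positive fraction in `[0, 1]`.
#' @param style `"binary"` or `"blobs"`.
#' @param seed integer seed.
#' @return list with `image` (an [image2d()]) and `true_fraction` (exact pixel
#'   fraction above 0.5 in the generated image).
#' @export
gen_area_image <- function(size = c(256L, 256L), positive_fraction = 0.3,
                           style = c("binary", "blobs"), seed = 1L) {
  style <- match.arg(style)
  if (length(size) != 2L || any(size < 1)) stopf("`size` must be two positive integers")
  assert_scalar_num(positive_fraction, "positive_fraction", 0, 1)
  nr <- as.integer(size[1]); nc <- as.integer(size[2]); n <- nr * nc
  with_seed(seed, {
    if (style == "binary") {
      k <- round(positive_fraction * n)
      img <- matrix(0, nr, nc)
      if (k > 0) img[sample.int(n, k)] <- 1
      true_fraction <- k / n
    } else {
      img <- matrix(0, nr, nc)
      target <- positive_fraction * n
      radius <- max(3, round(sqrt(n) / 16))
      guard <- 0L
      while (sum(img > 0.5) < target && guard < 10000L) {
        guard <- guard + 1L
        cx <- stats::runif(1, 1, nc); cy <- stats::runif(1, 1, nr)
        r <- radius * stats::runif(1, 0.6, 1.4)
        xs <- max(1, floor(cx - r - 2)):min(nc, ceiling(cx + r + 2))
        ys <- max(1, floor(cy - r - 2)):min(nr, ceiling(cy + r + 2))
        X <- matrix(xs, length(ys), length(xs), byrow = TRUE)
        Y <- matrix(ys, length(ys), length(xs))
        d <- sqrt((X - cx)^2 + (Y - cy)^2)
        # soft-edged disk: full intensity inside, 2 px linear falloff
        disk <- pmin(pmax((r - d) / 2 + 0.5, 0), 1)
        img[ys, xs] <- pmax(img[ys, xs], disk)
      }
      true_fraction <- sum(img > 0.5) / n
    }
    list(image = image2d(img), true_fraction = true_fraction)
  })
}
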