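# shared fixture builders; everything is generated in code at test time

# image of parallel full-width lines: every subregion sees the same edges,
# no caps, no noise — the cleanest possible input for the detector
parallel_line_image <- function(angle, size = 180L, spacing = 12L, width = 3) {
  canvas <- matrix(0, size, size)
  diag_len <- 2 * size
  n_lines <- ceiling(2 * diag_len / spacing)
  u <- c(cos(angle), sin(angle))                 # line direction
  v <- c(-sin(angle), cos(angle))                # normal
  ctr <- c(size / 2, size / 2)
  for (k in seq(-n_lines, n_lines)) {
    base <- ctr + k * spacing * v
    p1 <- base - diag_len * u; p2 <- base + diag_len * u
    canvas <- fiberarch:::draw_segment(canvas, p1, p2, width)
  }
  image2d(0.1 + 0.8 * canvas)
}

# rotate an image matrix by 90 degrees counterclockwise in (x, y) convention
rot90_mat <- function(m) t(m)[, nrow(m):1]

# minimal fiber_set carrying prescribed per-fiber metrics (for arithmetic
# checks that do not involve tracing)
make_fiber_set <- function(lengths, widths = rep(1, length(lengths)),
                           angles = rep(0, length(lengths)),
                           straightness = rep(1, length(lengths)),
                           image_size = c(100L, 100L),
                           raster = matrix(FALSE, image_size[1], image_size[2])) {
  fibers <- lapply(seq_along(lengths), function(i)
    list(centerline = rbind(c(1, 1), c(1 + lengths[i], 1)),
         length = lengths[i], width = widths[i], angle = angles[i],
         straightness = straightness[i]))
  structure(list(fibers = fibers, image_size = image_size,
                 centerline_raster = raster, n_fibers = length(fibers),
                 threshold = NA_real_),
            class = "fiber_set")
}

axial_err <- function(a, b) {
  d <- abs(wrap_axial(a) - wrap_axial(b))
  pmin(d, pi - d)
}

bessel_mvl <- function(kappa) besselI(kappa, 1) / besselI(kappa, 0)

# delta-method SE of the empirical resultant length of a von Mises sample
bessel_mvl_se <- function(kappa, n) {
  rho <- bessel_mvl(kappa)
  r2 <- besselI(kappa, 2) / besselI(kappa, 0)
  sqrt(((1 + r2) / 2 - rho^2) / n)
}
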