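#' @importFrom stats quantile sd
NULL

# edge-replicated shift: value at (r + dr, c + dc)
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

image_gradients <- function(px, operator = c("sobel", "central")) {
  operator <- match.arg(operator)
  if (operator == "sobel") {
    gx <- (shift_mat(px, -1, 1) + 2 * shift_mat(px, 0, 1) + shift_mat(px, 1, 1) -
           shift_mat(px, -1, -1) - 2 * shift_mat(px, 0, -1) - shift_mat(px, 1, -1)) / 8
    gy <- (shift_mat(px, 1, -1) + 2 * shift_mat(px, 1, 0) + shift_mat(px, 1, 1) -
           shift_mat(px, -1, -1) - 2 * shift_mat(px, -1, 0) - shift_mat(px, -1, 1)) / 8
  } else {
    gx <- (shift_mat(px, 0, 1) - shift_mat(px, 0, -1)) / 2
    gy <- (shift_mat(px, 1, 0) - shift_mat(px, -1, 0)) / 2
  }
  # the outermost ring only sees replicated pixels, which biases the gradient
  # direction toward the border axis; exclude it from the accumulation
  nr <- nrow(px); nc <- ncol(px)
  gx[c(1, nr), ] <- 0; gx[, c(1, nc)] <- 0
  gy[c(1, nr), ] <- 0; gy[, c(1, nc)] <- 0
  list(gx = gx, gy = gy)
}

#' Intensity-gradient fiber orientation field
#'
#' Detects the dominant fiber orientation in small square subregions by
#' accumulating pixel intensity gradients in doubled-angle space. Within each
#' subregion the gradient orientation resultant is
#' `sum_k m_k (cos 2 phi_k, sin 2 phi_k)` with `m_k` the gradient magnitude
#' and `phi_k` its direction; the fiber angle is the half-resultant direction
#' rotated by 90 degrees, since intensity gradients run perpendicular to
#' fiber edges. Subregions with little image structure (total gradient
#' magnitude below the `weight_cutoff_quantile` quantile) and subregions
#' touching the mask complement are dropped.
#'
#' @param image an [image2d()] (or matrix coercible to one).
#' @param subregion_px side of the square subregion in pixels, >= 3.
#' @param gradient_operator `"sobel"` (default) or `"central"` differences.
#' @param weight_cutoff_quantile drop subregions whose total gradient
#'   magnitude falls below this quantile of all candidate subregions;
#'   in `[0, 1]`, default 0.25.
#' @return an `orientation_field` data.frame with columns `cx`, `cy`
#'   (subregion centers, px), `theta` (axial angle, radians in `[0, pi)`) and
#'   `weight` (total gradient magnitude); `subregion_px` kept as an attribute.
#' @export
subregion_orientations <- function(image, subregion_px = 5L,
                                   gradient_operator = c("sobel", "central"),
                                   weight_cutoff_quantile = 0.25) {
  image <- as_image2d(image)
  s <- as.integer(subregion_px)
  if (s < 3L) stopf("`subregion_px` must be >= 3")
  assert_scalar_num(weight_cutoff_quantile, "weight_cutoff_quantile", 0, 1)
  px <- image$pixels
  nr <- nrow(px); nc <- ncol(px)
  if (nr < s || nc < s) stopf("image (%d x %d) is smaller than one %d px subregion", nr, nc, s)
  g <- image_gradients(px, gradient_operator)
  m2 <- g$gx^2 + g$gy^2           # squared magnitude
  m <- sqrt(m2)
  # magnitude-weighted doubled-angle components: m*cos(2phi), m*sin(2phi)
  c2 <- ifelse(m > 0, (g$gx^2 - g$gy^2) / m, 0)
  s2 <- ifelse(m > 0, 2 * g$gx * g$gy / m, 0)

  ntr <- nr %/% s; ntc <- nc %/% s
  ri <- seq_len(ntr * s); ci <- seq_len(ntc * s)
  tile_id <- (rep(ceiling(ri / s), times = length(ci)) - 1L) * ntc +
    rep(ceiling(ci / s), each = length(ri))
  sub <- function(x) as.vector(x[ri, ci, drop = FALSE])
  W <- rowsum(sub(m), tile_id)[, 1]
  C <- rowsum(sub(c2), tile_id)[, 1]
  S <- rowsum(sub(s2), tile_id)[, 1]
  tid <- as.integer(rownames(rowsum(sub(m), tile_id)))
  tr <- (tid - 1L) %/% ntc + 1L; tc <- (tid - 1L) %% ntc + 1L
  cx <- (tc - 0.5) * s; cy <- (tr - 0.5) * s

  keep <- W > 0
  if (!is.null(image$mask)) {
    bad <- rowsum(sub(1 - image$mask), tile_id)[, 1] > 0
    keep <- keep & !bad
  }
  if (any(keep)) {
    cutoff <- stats::quantile(W[keep], weight_cutoff_quantile, names = FALSE)
    # the 1e-9 relative floor discards tiles whose only "signal" is numerical
    # ripple (e.g. FFT blur residue), which would otherwise anchor the quantile
    keep <- keep & (W >= max(cutoff, 1e-9 * max(W))) & (sqrt(C^2 + S^2) > 0)
  }
  if (!any(keep))
    warnf("no subregion passed the gradient cutoff; returning an empty field")
  theta <- wrap_axial(atan2(S[keep], C[keep]) / 2 + pi / 2)
  out <- data.frame(cx = cx[keep], cy = cy[keep], theta = theta, weight = W[keep])
  attr(out, "subregion_px") <- s
  class(out) <- c("orientation_field", "data.frame")
  out
}

field_angles <- function(x) {
  if (inherits(x, "orientation_field")) x$theta
  else if (is.numeric(x)) wrap_axial(x)
  else stopf("expected an orientation field or a numeric angle vector")
}

#' Doubled-angle alignment summary
#'
#' Computes the mean vector length (MVL) of a set of axial angles: each angle
#' theta maps to a unit vector at the doubled angle 2*theta and the MVL is the
#' norm of the mean vector. MVL is 0 for completely random fiber alignment and
#' 1 for completely aligned fibers. Also reports the circular mean angle, a
#' weighted MVL variant, the circular standard deviation, an angle histogram,
#' and the recentred angle kurtosis and skewness.
#'
#' @param field an `orientation_field` from [subregion_orientations()], or a
#'   numeric vector of axial angles in radians.
#' @param weighted if `TRUE`, the primary `mvl` uses gradient-magnitude
#'   weights instead of one vote per subregion (both variants are always
#'   reported as `mvl` / `mvl_weighted`).
#' @param n_bins number of histogram bins on `[0, pi)`.
#' @return an `alignment_summary` list: `mvl`, `mvl_weighted`, `mean_angle`,
#'   `circ_sd`, `n_subregions`, `angle_histogram` (`breaks`, `counts`),
#'   `angle_kurtosis`, `angle_skewness`, `angle_entropy`,
#'   `angle_peak_fraction`.
#' @export
alignment_summary <- function(field, weighted = FALSE, n_bins = 18L) {
  theta <- field_angles(field)
  if (length(theta) == 0L) stopf("alignment summary is undefined on an empty field")
  w <- if (inherits(field, "orientation_field")) field$weight else rep(1, length(theta))
  cu <- mean(cos(2 * theta)); su <- mean(sin(2 * theta))
  mvl_unit <- sqrt(cu^2 + su^2)
  wn <- w / sum(w)
  cw <- sum(wn * cos(2 * theta)); sw <- sum(wn * sin(2 * theta))
  mvl_w <- sqrt(cw^2 + sw^2)
  if (weighted) { cm <- cw; sm <- sw } else { cm <- cu; sm <- su }
  mean_angle <- wrap_axial(atan2(sm, cm) / 2)
  breaks <- seq(0, pi, length.out = n_bins + 1L)
  counts <- tabulate(findInterval(theta, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = n_bins)
  p <- counts / sum(counts)
  ent <- { pp <- p[p > 0]; -sum(pp * log(pp)) / log(n_bins) }
  kur <- angle_kurtosis(theta, degenerate = "inf")
  structure(list(
    mvl = if (weighted) mvl_w else mvl_unit,
    mvl_unit = mvl_unit, mvl_weighted = mvl_w,
    mean_angle = mean_angle,
    circ_sd = sqrt(-2 * log(max(mvl_unit, 1e-15))),
    n_subregions = length(theta),
    angle_histogram = list(breaks = breaks, counts = counts),
    angle_kurtosis = kur,
    angle_skewness = angle_skewness(theta),
    angle_entropy = ent,
    angle_peak_fraction = max(p)), class = "alignment_summary")
}

#' @export
print.alignment_summary <- function(x, ...) {
  cat(sprintf("<alignment_summary> n = %d, MVL = %.3f, mean angle = %.1f deg, kurtosis = %.2f\n",
              x$n_subregions, x$mvl, x$mean_angle * 180 / pi, x$angle_kurtosis))
  invisible(x)
}

recentre_axial <- function(theta, center = c("circular_mean", "fixed"),
                           center_value = pi / 2) {
  center <- match.arg(center)
  mu <- if (center == "circular_mean")
    wrap_axial(atan2(mean(sin(2 * theta)), mean(cos(2 * theta))) / 2)
  else wrap_axial(center_value)
  # shift so the center maps to the interval midpoint pi/2, then unwrap
  (theta - mu + pi / 2) %% pi
}

#' Kurtosis of a recentred axial angle sample
#'
#' Angles are recentred so their circular mean (of doubled angles) sits at the
#' midpoint of `[0, pi)`, unwrapped to a linear sample, and the sample excess
#' kurtosis (fourth standardized moment minus 3; 0 for a Gaussian) is
#' returned. A uniform angle distribution gives -1.2.
#'
#' @param angles axial angles in radians, length >= 4.
#' @param center `"circular_mean"` (default) or `"fixed"` recentring.
#' @param center_value center used when `center = "fixed"`.
#' @param degenerate what to do when the recentred sample has zero variance:
#'   `"error"` (default) or `"inf"` to return `Inf` as a sentinel.
#' @return excess kurtosis (numeric scalar).
#' @export
angle_kurtosis <- function(angles, center = c("circular_mean", "fixed"),
                           center_value = pi / 2,
                           degenerate = c("error", "inf")) {
  degenerate <- match.arg(degenerate)
  theta <- wrap_axial(angles)
  if (length(theta) < 4L) stopf("angle kurtosis needs at least 4 angles")
  x <- recentre_axial(theta, center, center_value)
  x <- x - mean(x)
  m2 <- mean(x^2)
  if (m2 < 1e-20) {
    if (degenerate == "error") stopf("angle kurtosis is undefined: zero angular variance")
    return(Inf)
  }
  mean(x^4) / m2^2 - 3
}

# third standardized moment of the recentred, unwrapped angle sample
angle_skewness <- function(angles) {
  theta <- wrap_axial(angles)
  if (length(theta) < 3L) return(NA_real_)
  x <- recentre_axial(theta)
  x <- x - mean(x)
  m2 <- mean(x^2)
  if (m2 < 1e-20) return(0)
  mean(x^3) / m2^1.5
}

#' Cell alignment from a fluorescence image
#'
#' Convenience composition of [subregion_orientations()] and
#' [alignment_summary()] for images of stained elongated cells (e.g.
#' phalloidin-labelled fibroblasts); the mathematics is identical to the
#' fiber analysis.
#'
#' @inheritParams subregion_orientations
#' @param weighted passed to [alignment_summary()].
#' @return an `alignment_summary`.
#' @export
cell_alignment <- function(image, subregion_px = 5L,
                           gradient_operator = c("sobel", "central"),
                           weight_cutoff_quantile = 0.25, weighted = FALSE) {
  field <- subregion_orientations(image, subregion_px, gradient_operator,
                                  weight_cutoff_quantile)
  alignment_summary(field, weighted = weighted)
}

#' Write an orientation field to CSV
#'
#' Columns: `cx`, `cy`, `theta_deg`, `weight`.
#'
#' @param field an `orientation_field`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_orientation_csv <- function(field, path) {
  utils::write.csv(data.frame(cx = field$cx, cy = field$cy,
                              theta_deg = field$theta * 180 / pi,
                              weight = field$weight),
                   path, row.names = FALSE)
  invisible(path)
}
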