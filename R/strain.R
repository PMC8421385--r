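#' Least-squares homogeneous deformation from matched markers
#'
#' Fits the overdetermined linear map `x = F X + p` carrying reference marker
#' positions to deformed positions: `F` is the 2 x 2 homogeneous deformation
#' gradient and `p` a translation absorbing any rigid offset between images.
#' Solved by QR orthogonal factorization of the design `[X1 X2 1]`; with
#' noiseless affine data the fit recovers the generator to machine precision.
#'
#' @param markers a [marker_pair()] (>= 3 non-collinear markers).
#' @return a `deformation_result`: `F`, `p`, `residual_rms` (RMS over all
#'   `2 n` scalar residual components), `n_markers`, `condition` (design
#'   condition number).
#' @export
fit_deformation <- function(markers) {
  if (!inherits(markers, "marker_pair")) stopf("`markers` must be a marker_pair")
  X <- markers$X; x <- markers$x
  n <- nrow(X)
  A <- cbind(X, 1)
  sv <- svd(A)$d
  cond <- sv[1] / sv[length(sv)]
  if (!is.finite(cond) || cond > 1e8 || sv[length(sv)] < 1e-12)
    stopf("markers are (near-)collinear: design condition number %.3g; the deformation is not identifiable", cond)
  coef <- qr.solve(A, x)           # 3 x 2: rows (F.1, F.2, p) per output coord
  Fhat <- t(coef[1:2, , drop = FALSE])
  p <- as.numeric(coef[3, ])
  res <- x - A %*% coef
  if (det(Fhat) <= 0) warnf("fitted deformation has non-positive determinant (det F = %.3g)", det(Fhat))
  structure(list(F = Fhat, p = p,
                 residual_rms = sqrt(mean(res^2)),
                 n_markers = n, condition = cond),
            class = "deformation_result")
}

#' @export
print.deformation_result <- function(x, ...) {
  cat(sprintf("<deformation_result> n = %d markers\nF = [%.4f %.4f; %.4f %.4f], p = (%.3f, %.3f), residual RMS = %.3g\n",
              x$n_markers, x$F[1, 1], x$F[1, 2], x$F[2, 1], x$F[2, 2],
              x$p[1], x$p[2], x$residual_rms))
  invisible(x)
}

#' Green-Lagrange strain from a deformation gradient
#'
#' Converts the deformation gradient to the finite-strain tensor
#' `E = 1/2 (F^T F - I)`, which vanishes for any rigid motion. The `form`
#' argument also offers the variant `E = 1/2 ((F^T F)^2 - I)` for
#' comparison with conversions that square the right Cauchy-Green tensor.
#' Principal strains and directions come from the eigendecomposition of `E`,
#' sorted by descending strain with ties broken by ascending direction angle.
#'
#' @param F 2 x 2 deformation gradient (or a `deformation_result`).
#' @param form `"standard"` (default) or `"printed"` (squared variant).
#' @return a `strain_tensor`: `E`, `principal_strains` (descending),
#'   `principal_directions` (unit column vectors), `form`.
#' @export
green_lagrange <- function(F, form = c("standard", "printed")) {
  form <- match.arg(form)
  if (inherits(F, "deformation_result")) F <- F$F
  F <- matrix(as.numeric(F), 2, 2)
  if (any(!is.finite(F))) stopf("`F` must be finite")
  C <- t(F) %*% F
  E <- if (form == "standard") (C - diag(2)) / 2 else (C %*% C - diag(2)) / 2
  E <- (E + t(E)) / 2
  eg <- eigen(E, symmetric = TRUE)
  vals <- eg$values; vecs <- eg$vectors
  if (abs(vals[1] - vals[2]) < 1e-14) {
    ang <- wrap_axial(atan2(vecs[2, ], vecs[1, ]))
    ord <- order(ang)
    vals <- vals[ord]; vecs <- vecs[, ord, drop = FALSE]
  }
  # deterministic eigenvector signs: first nonzero component positive
  for (j in 1:2) if (vecs[which(abs(vecs[, j]) > 1e-12)[1], j] < 0) vecs[, j] <- -vecs[, j]
  structure(list(E = E, principal_strains = vals,
                 principal_directions = vecs, form = form),
            class = "strain_tensor")
}

#' @export
print.strain_tensor <- function(x, ...) {
  cat(sprintf("<strain_tensor> E = [%.4f %.4f; %.4f %.4f]; principal strains %.4f, %.4f\n",
              x$E[1, 1], x$E[1, 2], x$E[2, 1], x$E[2, 2],
              x$principal_strains[1], x$principal_strains[2]))
  invisible(x)
}

#' Principal engineering stretch, in percent
#'
#' Reports `100 (sqrt(lambda_i(F^T F)) - 1)` along each principal direction —
#' the engineering strain a "10 percent equibiaxial strain" protocol targets —
#' together with their mean and the stretch anisotropy ratio.
#'
#' @param result a `deformation_result` or a 2 x 2 deformation gradient.
#' @return list with `percent` (two values, descending), `mean_percent`,
#'   `anisotropy` (larger/smaller principal stretch).
#' @export
equibiaxial_strain_percent <- function(result) {
  F <- if (inherits(result, "deformation_result")) result$F else matrix(as.numeric(result), 2, 2)
  if (det(F) <= 0) warnf("non-physical deformation: det F = %.3g <= 0", det(F))
  lam <- sort(eigen(t(F) %*% F, symmetric = TRUE)$values, decreasing = TRUE)
  stretches <- sqrt(pmax(lam, 0))
  pct <- 100 * (stretches - 1)
  list(percent = pct, mean_percent = mean(pct),
       anisotropy = stretches[1] / stretches[2])
}

#' Write strain-fit results as JSON
#'
#' @param result a `deformation_result`.
#' @param path JSON path.
#' @param form Green-Lagrange variant to report.
#' @return `path`, invisibly.
#' @export
write_strain_json <- function(result, path, form = "standard") {
  st <- green_lagrange(result$F, form = form)
  eb <- equibiaxial_strain_percent(result)
  jsonlite::write_json(list(
    F = as.numeric(t(result$F)), p = result$p,
    residual_rms = result$residual_rms, n_markers = result$n_markers,
    E = as.numeric(t(st$E)), principal_strains = st$principal_strains,
    stretch_percent = eb$percent, mean_stretch_percent = eb$mean_percent,
    anisotropy = eb$anisotropy),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
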