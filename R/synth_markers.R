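#' Matched fiducial-marker coordinate pair
#'
#' Holds reference (undeformed) marker positions `X` and deformed positions
#' `x`; correspondence is by row index. At least three non-collinear markers
#' are needed to determine a homogeneous deformation.
#'
#' @param X n x 2 numeric matrix of reference positions.
#' @param x n x 2 numeric matrix of deformed positions, same order.
#' @return object of class `marker_pair`.
#' @export
marker_pair <- function(X, x) {
  X <- as.matrix(X); x <- as.matrix(x)
  if (ncol(X) != 2L || ncol(x) != 2L) stopf("marker coordinates must be n x 2")
  if (nrow(X) != nrow(x)) stopf("X and x must hold the same number of markers")
  if (nrow(X) < 3L) stopf("at least 3 markers are required")
  if (any(!is.finite(X)) || any(!is.finite(x))) stopf("marker coordinates must be finite")
  structure(list(X = unname(X), x = unname(x)), class = "marker_pair")
}

#' Simulate a tracked marker grid under a known affine deformation
#'
#' Generates a regular grid of fiducial markers (default 3 x 3, mirroring a
#' nine-dot surface-marker protocol), maps it through
#' `x = F_true X + p_true`, and adds isotropic Gaussian localization noise.
#'
#' @param F_true 2 x 2 deformation gradient; must be invertible.
#' @param p_true translation 2-vector.
#' @param grid `c(rows, cols, spacing)`; the grid is centered on the origin.
#' @param noise_sigma sd of marker localization noise (same units as spacing).
#' @param seed integer seed.
#' @return a [marker_pair()].
#' @export
gen_marker_pair <- function(F_true = diag(2), p_true = c(0, 0),
                            grid = c(3, 3, 10), noise_sigma = 0, seed = 1L) {
  F_true <- matrix(as.numeric(F_true), 2, 2)
  if (any(!is.finite(F_true)) || abs(det(F_true)) < 1e-12)
    stopf("`F_true` must be a finite, invertible 2 x 2 matrix")
  if (length(grid) != 3L || any(grid[1:2] < 1) || grid[1] * grid[2] < 3)
    stopf("`grid` must give >= 3 markers")
  if (grid[1] == 1L || grid[2] == 1L)
    stopf("grid markers must not be collinear (need rows >= 2 and cols >= 2)")
  assert_scalar_num(noise_sigma, "noise_sigma", lower = 0)
  rows <- grid[1]; cols <- grid[2]; sp <- grid[3]
  gx <- (seq_len(cols) - (cols + 1) / 2) * sp
  gy <- (seq_len(rows) - (rows + 1) / 2) * sp
  X <- as.matrix(expand.grid(X1 = gx, X2 = gy))
  x <- X %*% t(F_true) + matrix(p_true, nrow(X), 2, byrow = TRUE)
  if (noise_sigma > 0)
    x <- x + with_seed(seed, matrix(stats::rnorm(length(x), 0, noise_sigma), nrow(x), 2))
  marker_pair(X, x)
}

#' Read / write marker coordinate CSV
#'
#' The on-disk format has columns `id, X1, X2, x1, x2`.
#'
#' @param markers a [marker_pair()].
#' @param path CSV path.
#' @return `write_markers_csv` returns `path` invisibly; `read_markers_csv`
#'   returns a [marker_pair()].
#' @export
write_markers_csv <- function(markers, path) {
  df <- data.frame(id = seq_len(nrow(markers$X)),
                   X1 = markers$X[, 1], X2 = markers$X[, 2],
                   x1 = markers$x[, 1], x2 = markers$x[, 2])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_markers_csv
#' @export
read_markers_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("X1", "X2", "x1", "x2")
  if (!all(need %in% names(df)))
    stopf("marker CSV must have columns id, X1, X2, x1, x2")
  marker_pair(as.matrix(df[, c("X1", "X2")]), as.matrix(df[, c("x1", "x2")]))
}
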