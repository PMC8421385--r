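`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
  if (x < lower || x > upper)
    stopf("`%s` must be in [%s, %s], got %s", name, lower, upper, x)
  invisible(x)
}

#' Wrap angles onto the axial interval [0, pi)
#'
#' Fiber orientation is axial: an angle theta and theta + pi describe the same
#' fiber. All orientation angles in this package live on `[0, pi)`.
#'
#' @param theta numeric vector of angles in radians.
#' @return angles wrapped to `[0, pi)`.
#' @export
wrap_axial <- function(theta) {
  out <- theta %% pi
  # guard against pi itself from floating-point roundoff
  out[out >= pi] <- 0
  out
}

#' Sample from the von Mises distribution
#'
#' Best-Fisher rejection sampler. With `kappa = 0` the distribution is uniform
#' on the circle. Used by the synthetic fiber generator to draw doubled
#' orientation angles.
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration parameter, >= 0.
#' @return numeric vector of angles in `(-pi, pi] + mu`, length `n`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  assert_scalar_num(kappa, "kappa", lower = 0)
  if (n == 0L) return(numeric(0))
  if (kappa == 0) return(stats::runif(n, mu - pi, mu + pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- max(n - got, 16L)
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    nacc <- sum(ok)
    if (nacc > 0L) {
      take <- min(nacc, n - got)
      acc <- which(ok)[seq_len(take)]
      out[got + seq_len(take)] <- mu + sign(u3[acc] - 0.5) * acos(pmax(pmin(f[acc], 1), -1))
      got <- got + take
    }
  }
  out
}

#' Sample axial fiber angles with a von Mises doubled-angle law
#'
#' Draws orientations theta in `[0, pi)` such that the doubled angles
#' `2*theta` follow von Mises(2*mean_angle, kappa). This is the standard
#' construction for concentrated axial data; `kappa = 0` gives isotropy and
#' `kappa = Inf` collapses to `mean_angle` exactly.
#'
#' @param n number of angles.
#' @param mean_angle preferred orientation, radians in `[0, pi)`.
#' @param kappa concentration of the doubled-angle distribution, >= 0.
#' @return axial angles in `[0, pi)`.
#' @export
raxial_angles <- function(n, mean_angle = 0, kappa = 2) {
  if (is.infinite(kappa)) return(rep(wrap_axial(mean_angle), n))
  phi <- rvonmises(n, mu = 2 * mean_angle, kappa = kappa)
  wrap_axial(phi / 2)
}

#' Expected mean vector length of a von Mises sample
#'
#' The population resultant length of von Mises(mu, kappa) is the Bessel ratio
#' I1(kappa)/I0(kappa). Computed here by direct numerical quadrature of the
#' resultant integral rather than `besselI`, so it can serve as an independent
#' oracle for the circular statistics.
#'
#' @param kappa concentration, >= 0.
#' @return expected resultant length in `[0, 1]`.
#' @export
vonmises_mvl_expected <- function(kappa) {
  vapply(kappa, function(k) {
    if (k == 0) return(0)
    num <- stats::integrate(function(t) cos(t) * exp(k * cos(t)), -pi, pi,
                            rel.tol = 1e-10)$value
    den <- stats::integrate(function(t) exp(k * cos(t)), -pi, pi,
                            rel.tol = 1e-10)$value
    num / den
  }, numeric(1))
}

# run expr with a local RNG state seeded from `seed` (global state untouched)
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
      stopf("`seed` must be a single integer")
    return(withr::with_seed(as.integer(seed), expr))
  }
  expr
}
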