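test_that("identity motion fits to identity with zero residual", {
  fit <- fit_deformation(gen_marker_pair(diag(2), c(0, 0)))
  expect_equal(fit$F, diag(2), tolerance = 1e-12)
  expect_equal(fit$p, c(0, 0), tolerance = 1e-12)
  expect_lt(fit$residual_rms, 1e-12)
  expect_equal(fit$n_markers, 9L)
})

test_that("noiseless affine maps are recovered to machine precision", {
  withr::with_seed(41, {
    for (i in 1:50) {
      F_true <- diag(2) + matrix(runif(4, -0.2, 0.2), 2, 2)
      if (abs(det(F_true)) < 0.1) next
      p_true <- runif(2, -5, 5)
      fit <- fit_deformation(gen_marker_pair(F_true, p_true, noise_sigma = 0))
      expect_lt(max(abs(fit$F - F_true)) / max(abs(F_true)), 1e-10)
      expect_lt(max(abs(fit$p - p_true)), 1e-8)
      expect_lt(fit$residual_rms, 1e-10)
    }
  })
})

test_that("degenerate marker configurations are rejected with diagnostics", {
  expect_error(marker_pair(matrix(1:4, 2, 2), matrix(1:4, 2, 2)), "at least 3")
  collinear <- cbind(1:5, 2 * (1:5))
  expect_error(fit_deformation(marker_pair(collinear, collinear)),
               "collinear.*condition")
})

test_that("least-squares estimates behave per theory under noise", {
  withr::with_seed(43, {
    sims <- t(replicate(200, {
      fit <- fit_deformation(gen_marker_pair(diag(c(1.1, 1.1)), c(3, -2),
                                             noise_sigma = 0.5,
                                             seed = sample.int(1e6, 1)))
      c(diag(fit$F), fit$residual_rms)
    }))
  })
  # unbiased F recovery
  expect_lt(abs(mean(sims[, 1]) - 1.1), 3 * sd(sims[, 1]) / sqrt(200))
  expect_lt(abs(mean(sims[, 2]) - 1.1), 3 * sd(sims[, 2]) / sqrt(200))
  # residual rms deflated by the 6 fitted parameters: sigma*sqrt(1 - 6/(2n))
  theory <- 0.5 * sqrt(1 - 6 / 18)
  expect_lt(abs(mean(sims[, 3]) - theory), 3 * sd(sims[, 3]) / sqrt(200))
})

test_that("Green-Lagrange strain matches closed forms", {
  expect_equal(green_lagrange(diag(2))$E, matrix(0, 2, 2), tolerance = 1e-15)
  st <- green_lagrange(diag(c(1.1, 1.1)))
  expect_equal(st$E, diag(c(0.105, 0.105)), tolerance = 1e-12)
  expect_equal(st$principal_strains, c(0.105, 0.105), tolerance = 1e-12)
  # the squared-tensor variant: ((1.21)^2 - 1)/2 = 0.23205
  stp <- green_lagrange(diag(c(1.1, 1.1)), form = "printed")
  expect_equal(diag(stp$E), c(0.23205, 0.23205), tolerance = 1e-10)
  expect_error(green_lagrange(matrix(c(1, NA, 0, 1), 2, 2)), "finite")
})

test_that("strain is blind to rigid motion", {
  R <- function(a) matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  withr::with_seed(44, {
    for (a in runif(20, 0, 2 * pi)) {
      expect_equal(green_lagrange(R(a))$E, matrix(0, 2, 2), tolerance = 1e-12)
      F0 <- diag(c(1.15, 0.95))
      expect_equal(green_lagrange(R(a) %*% F0)$E, green_lagrange(F0)$E,
                   tolerance = 1e-12)
    }
  })
  # translation shifts only p, never F or E
  mp <- gen_marker_pair(diag(c(1.2, 0.9)), c(0, 0))
  mp_shift <- marker_pair(mp$X, mp$x + matrix(c(5, -7), 9, 2, byrow = TRUE))
  f1 <- fit_deformation(mp); f2 <- fit_deformation(mp_shift)
  expect_equal(f2$F, f1$F, tolerance = 1e-12)
  expect_equal(f2$p, f1$p + c(5, -7), tolerance = 1e-10)
})

test_that("the fit agrees with direct numerical minimization", {
  obj <- function(par, X, x) {
    Fm <- matrix(par[1:4], 2, 2); p <- par[5:6]
    sum((x - X %*% t(Fm) - matrix(p, nrow(X), 2, byrow = TRUE))^2)
  }
  withr::with_seed(45, {
    for (i in 1:50) {
      F_true <- diag(2) + matrix(runif(4, -0.3, 0.3), 2, 2)
      mp <- gen_marker_pair(F_true, runif(2, -3, 3), noise_sigma = 0.2,
                            seed = sample.int(1e6, 1))
      fit <- fit_deformation(mp)
      opt <- optim(c(1, 0, 0, 1, 0, 0), obj, X = mp$X, x = mp$x,
                   method = "BFGS", control = list(reltol = 1e-14, maxit = 1000))
      expect_lt(max(abs(c(as.vector(fit$F), fit$p) -
                          c(opt$par[1:4], opt$par[5:6]))), 1e-5)
    }
  })
})

test_that("engineering stretch percentages follow the definition", {
  expect_equal(equibiaxial_strain_percent(diag(2))$percent, c(0, 0))
  eb <- equibiaxial_strain_percent(diag(c(1.1, 1.1)))
  expect_equal(eb$percent, c(10, 10), tolerance = 1e-12)
  expect_equal(eb$anisotropy, 1, tolerance = 1e-12)
  uni <- equibiaxial_strain_percent(diag(c(1.2, 1.0)))
  expect_equal(uni$percent, c(20, 0), tolerance = 1e-12)
  expect_equal(uni$anisotropy, 1.2, tolerance = 1e-12)
  expect_warning(equibiaxial_strain_percent(diag(c(-1, 1))), "non-physical")
})

test_that("marker CSV round-trips and strain JSON reports the protocol quantities", {
  mp <- gen_marker_pair(diag(c(1.1, 1.1)), c(1, 2), noise_sigma = 0.05, seed = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_markers_csv(mp, f)
  mp2 <- read_markers_csv(f)
  expect_equal(mp2$X, mp$X, tolerance = 1e-12)
  expect_equal(mp2$x, mp$x, tolerance = 1e-12)
  j <- withr::local_tempfile(fileext = ".json")
  write_strain_json(fit_deformation(mp), j)
  out <- jsonlite::read_json(j, simplifyVector = TRUE)
  expect_equal(unlist(out$stretch_percent), c(10, 10), tolerance = 1)
})
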