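test_that("detector recovers the angle of parallel lines within 2 degrees", {
  for (ang in c(pi / 6, pi / 2, 2 * pi / 3)) {
    img <- parallel_line_image(ang)
    f <- subregion_orientations(img)
    expect_gt(nrow(f), 100)
    expect_true(all(axial_err(f$theta, ang) < 2 * pi / 180))
  }
})

test_that("a constant image yields an empty field and an undefined summary", {
  img <- image2d(matrix(0.5, 64, 64))
  expect_warning(f <- subregion_orientations(img), "empty")
  expect_equal(nrow(f), 0L)
  expect_error(alignment_summary(f), "empty")
  expect_error(subregion_orientations(image2d(matrix(0.5, 4, 4)), subregion_px = 5),
               "smaller")
  expect_error(subregion_orientations(img, subregion_px = 2), ">= 3")
})

test_that("rotating the image by 90 degrees shifts angles by 90 degrees mod pi", {
  g <- gen_fiber_image(fiber_sim_params(n_fibers = 30, kappa = Inf,
                                        mean_angle = pi / 6, noise_sigma = 0,
                                        seed = 5))
  s1 <- alignment_summary(subregion_orientations(g$image))
  s2 <- alignment_summary(subregion_orientations(image2d(rot90_mat(g$image$pixels))))
  expect_lt(axial_err(s2$mean_angle, s1$mean_angle + pi / 2), 3 * pi / 180)
  expect_lt(abs(s2$mvl - s1$mvl), 0.05)
})

test_that("orientation estimates are invariant to affine intensity rescaling", {
  g <- gen_fiber_image(fiber_sim_params(n_fibers = 25, seed = 8))
  f1 <- subregion_orientations(g$image)
  f2 <- subregion_orientations(image2d(0.1 + 0.5 * g$image$pixels))
  expect_equal(f2$theta, f1$theta, tolerance = 1e-10)
  expect_equal(alignment_summary(f2)$mvl, alignment_summary(f1)$mvl,
               tolerance = 1e-10)
})

test_that("MVL spans its endpoints and matches the von Mises expectation", {
  expect_identical(alignment_summary(rep(pi / 6, 100))$mvl, 1)
  expect_equal(alignment_summary(c(0, pi / 4, pi / 2, 3 * pi / 4))$mvl, 0,
               tolerance = 1e-15)
  for (kappa in c(0.5, 1, 2, 4)) {
    a <- withr::with_seed(20 + kappa, raxial_angles(1e4, 0.8, kappa))
    s <- alignment_summary(a)
    expect_lt(abs(s$mvl - bessel_mvl(kappa)), 3 * bessel_mvl_se(kappa, 1e4))
    expect_true(s$mvl >= 0 && s$mvl <= 1)
  }
})

test_that("alignment summary histogram and mean angle are coherent", {
  a <- withr::with_seed(3, raxial_angles(500, 1.1, 3))
  s <- alignment_summary(a)
  expect_equal(sum(s$angle_histogram$counts), s$n_subregions)
  expect_lt(axial_err(s$mean_angle, 1.1), 0.1)
  # weighted and unweighted variants coincide for unit weights
  expect_equal(s$mvl_weighted, s$mvl_unit, tolerance = 1e-12)
})

test_that("angle kurtosis matches distributional oracles", {
  # uniform angles: Monte-Carlo oracle band around the asymptotic -1.2
  k_unif <- withr::with_seed(31, angle_kurtosis(runif(1e5, 0, pi)))
  expect_lt(abs(k_unif - (-1.2)), 0.02)
  # tight Gaussian cluster: excess kurtosis near 0 (3 * MC se = 0.134)
  k_norm <- withr::with_seed(32,
    angle_kurtosis(wrap_axial(pi / 2 + rnorm(1e4, 0, 5 * pi / 180))))
  expect_lt(abs(k_norm), 0.14)
  # recentring handles clusters straddling the wrap point
  k_wrap <- withr::with_seed(33,
    angle_kurtosis(wrap_axial(rnorm(1e4, 0, 5 * pi / 180))))
  expect_lt(abs(k_wrap), 0.14)
})

test_that("angle kurtosis rejects degenerate inputs per configuration", {
  expect_error(angle_kurtosis(c(0.1, 0.2, 0.3)), "at least 4")
  expect_error(angle_kurtosis(rep(0.7, 10)), "zero angular variance")
  expect_identical(angle_kurtosis(rep(0.7, 10), degenerate = "inf"), Inf)
})

test_that("cell alignment composes the detector and the summary", {
  img <- parallel_line_image(0)
  s <- cell_alignment(img)
  expect_s3_class(s, "alignment_summary")
  expect_gt(s$mvl, 0.95)
  expect_lt(axial_err(s$mean_angle, 0), 2 * pi / 180)
  # isotropic fibers: mvl near the null sampling bound
  g <- gen_fiber_image(fiber_sim_params(n_fibers = 60, kappa = 0,
                                        noise_sigma = 0, seed = 12))
  s0 <- cell_alignment(g$image, weighted = TRUE)
  expect_lt(s0$mvl, 3 / sqrt(s0$n_subregions) + 0.15)
  # stability across subregion sizes
  s5 <- cell_alignment(g$image, subregion_px = 5, weighted = TRUE)
  s9 <- cell_alignment(g$image, subregion_px = 9, weighted = TRUE)
  expect_lt(abs(s5$mvl - s9$mvl), 0.1)
})
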