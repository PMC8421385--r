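test_that("fiber image generation is deterministic and records exact ground truth", {
  p <- fiber_sim_params(n_fibers = 15, seed = 42L)
  a <- gen_fiber_image(p)
  b <- gen_fiber_image(p)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth$angles, b$truth$angles)
  expect_equal(length(a$truth$angles), length(a$truth$lengths))
  expect_equal(length(a$truth$angles), length(a$truth$polylines))
  expect_true(all(a$truth$angles >= 0 & a$truth$angles < pi))
  expect_true(a$truth$mvl_true >= 0 && a$truth$mvl_true <= 1)
  # recorded polylines match recorded lengths
  lens <- vapply(a$truth$polylines, function(m) sqrt(sum((m[2, ] - m[1, ])^2)),
                 numeric(1))
  expect_equal(lens, a$truth$lengths)
})

test_that("ground-truth MVL hits the analytic endpoints", {
  all_same <- gen_fiber_image(fiber_sim_params(n_fibers = 20, kappa = Inf,
                                               mean_angle = pi / 4, seed = 1))
  expect_identical(all_same$truth$mvl_true, 1)
  # stratified quartet 0/45/90/135 degrees: doubled-angle vectors cancel
  quartet <- c(0, pi / 4, pi / 2, 3 * pi / 4)
  mvl <- sqrt(mean(cos(2 * quartet))^2 + mean(sin(2 * quartet))^2)
  expect_equal(mvl, 0, tolerance = 1e-15)
})

test_that("sampled doubled angles follow the von Mises concentration law", {
  for (kappa in c(0.5, 1, 2, 4)) {
    a <- withr::with_seed(7 + kappa, raxial_angles(1e4, pi / 3, kappa))
    mvl <- sqrt(mean(cos(2 * a))^2 + mean(sin(2 * a))^2)
    expect_lt(abs(mvl - bessel_mvl(kappa)), 3 * bessel_mvl_se(kappa, 1e4))
    # quadrature oracle agrees with the Bessel ratio
    expect_equal(vonmises_mvl_expected(kappa), bessel_mvl(kappa), tolerance = 1e-8)
  }
  expect_equal(vonmises_mvl_expected(0), 0)
})

test_that("fiber image generation rejects invalid parameters", {
  expect_error(fiber_sim_params(image_size_px = c(0, 10)), "positive")
  expect_error(fiber_sim_params(kappa = -1), "kappa")
  expect_error(fiber_sim_params(fg_intensity = 0.1, bg_intensity = 0.5),
               "bg_intensity")
})

test_that("marker generation maps the grid through the exact affine law", {
  id <- gen_marker_pair(diag(2), c(0, 0), noise_sigma = 0)
  expect_equal(id$x, id$X)
  expect_equal(nrow(id$X), 9L)  # default nine-dot grid
  sc <- gen_marker_pair(diag(c(1.1, 1.1)), c(0, 0), noise_sigma = 0)
  expect_equal(sc$x, 1.1 * sc$X, tolerance = 1e-14)
  expect_error(gen_marker_pair(matrix(0, 2, 2)), "invertible")
  expect_error(gen_marker_pair(diag(2), grid = c(1, 9, 5)), "collinear")
})

test_that("noisy marker displacement is reproducible with empirical sd near sigma", {
  a <- gen_marker_pair(diag(2), c(0, 0), grid = c(30, 30, 5),
                       noise_sigma = 0.3, seed = 11)
  b <- gen_marker_pair(diag(2), c(0, 0), grid = c(30, 30, 5),
                       noise_sigma = 0.3, seed = 11)
  expect_identical(a$x, b$x)
  resid <- a$x - a$X
  expect_lt(abs(sd(as.vector(resid)) - 0.3), 3 * 0.3 / sqrt(2 * 900))
})

test_that("area image truth equals the exact pixel fraction", {
  blank <- gen_area_image(c(64, 64), 0, seed = 1)
  expect_equal(blank$true_fraction, 0)
  expect_equal(max(blank$image$pixels), 0)
  full <- gen_area_image(c(64, 64), 1, seed = 1)
  expect_equal(full$true_fraction, 1)
  g <- gen_area_image(c(100, 100), 0.30, "binary", seed = 3)
  expect_equal(g$true_fraction, 0.30, tolerance = 1 / 1e4)
  expect_equal(sum(g$image$pixels > 0.5) / 1e4, g$true_fraction)
  blobs <- gen_area_image(c(128, 128), 0.25, "blobs", seed = 4)
  expect_equal(sum(blobs$image$pixels > 0.5) / 128^2, blobs$true_fraction)
})

test_that("feature panel simulation honors shapes, labels, and determinism", {
  pan <- gen_feature_panel(c(W = 9, W_H = 9, W_HF = 7, UW = 6), seed = 5)
  expect_s3_class(pan, "feature_panel")
  expect_equal(dim(pan), c(31L, 26L))  # sample + group + 24 features
  expect_equal(as.vector(table(factor(pan$group, levels = c("W", "W_H", "W_HF", "UW")))),
               c(9L, 9L, 7L, 6L))
  expect_identical(pan, gen_feature_panel(c(W = 9, W_H = 9, W_HF = 7, UW = 6), seed = 5))
  expect_error(gen_feature_panel(c(4, 4), group_means = matrix(0, 3, 24)), "24")
  expect_error(gen_feature_panel(c(4, 4), group_sds = -1), "group_sds")
})
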