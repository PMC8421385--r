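test_that("disjoint straight fibers are recovered with their geometry", {
  g <- gen_fiber_image(fiber_sim_params(n_fibers = 12, kappa = 0,
                                        placement = "nonoverlap", seed = 9))
  fs <- extract_fibers(g$image)
  expect_equal(fs$n_fibers, length(g$truth$angles))
  lens <- sort(vapply(fs$fibers, `[[`, numeric(1), "length"))
  truth <- sort(g$truth$lengths)
  expect_lt(mean(abs(lens - truth) / truth), 0.05)
  expect_true(all(vapply(fs$fibers, `[[`, numeric(1), "straightness") > 0.9))
  df <- as.data.frame(fs)
  expect_equal(nrow(df), fs$n_fibers)
  expect_true(all(df$straightness <= 1 & df$length > 0))
})

test_that("a single drawn segment is traced with its length, angle and straightness", {
  canvas <- matrix(0, 120, 120)
  canvas <- fiberarch:::draw_segment(canvas, c(15, 15), c(105, 105), 3)
  fs <- extract_fibers(image2d(0.1 + 0.8 * canvas))
  expect_equal(fs$n_fibers, 1L)
  L <- sqrt(2) * 90
  expect_lt(abs(fs$fibers[[1]]$length - L) / L, 0.05)
  expect_gte(fs$fibers[[1]]$straightness, 0.99)
  expect_lt(axial_err(fs$fibers[[1]]$angle, pi / 4), 2 * pi / 180)
})

test_that("blank and constant images give an empty fiber set, not an error", {
  fs <- extract_fibers(image2d(matrix(0.05, 80, 80)))
  expect_equal(fs$n_fibers, 0L)
  m <- fiber_metrics(fs)
  expect_true(m$empty)
  expect_equal(m$n_fibers, 0L)
  expect_true(is.na(m$length_mean))
  expect_equal(m$box_density, 0)
})

test_that("extraction is invariant to content translation and monotone in min length", {
  canvas <- matrix(0, 150, 150)
  canvas <- fiberarch:::draw_segment(canvas, c(30, 40), c(90, 70), 3)
  canvas <- fiberarch:::draw_segment(canvas, c(40, 100), c(110, 120), 3)
  img1 <- image2d(0.1 + 0.8 * canvas)
  shifted <- matrix(0, 150, 150)
  shifted[11:150, 11:150] <- canvas[1:140, 1:140]
  img2 <- image2d(0.1 + 0.8 * shifted)
  f1 <- extract_fibers(img1); f2 <- extract_fibers(img2)
  expect_equal(f2$n_fibers, f1$n_fibers)
  expect_equal(sort(vapply(f2$fibers, `[[`, numeric(1), "length")),
               sort(vapply(f1$fibers, `[[`, numeric(1), "length")),
               tolerance = 0.03)
  # raising the minimum length never increases the count
  counts <- vapply(c(5, 20, 50, 80), function(ml)
    extract_fibers(img1, min_fiber_len_px = ml)$n_fibers, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("per-fiber summary arithmetic matches hand computation", {
  fs <- make_fiber_set(lengths = c(10, 30), widths = c(2, 4),
                       image_size = c(512L, 512L),
                       raster = matrix(FALSE, 512, 512))
  m <- fiber_metrics(fs)
  expect_equal(m$length_mean, 20)
  expect_equal(m$length_sd, sqrt(200), tolerance = 1e-12)  # 14.142
  expect_equal(m$n_fibers, 2L)
  expect_equal(m$feature_number, 2 / 512^2)
  expect_equal(m$width_mean, 3)
  # physical units scale lengths and areas
  mp <- fiber_metrics(fs, pixel_size = 0.5)
  expect_equal(mp$length_mean, 10)
  expect_equal(mp$feature_number, 2 / (512^2 * 0.25))
})

test_that("box density follows the counting definition", {
  empty <- make_fiber_set(numeric(0), image_size = c(100L, 100L))
  expect_equal(box_density(empty, box_px = 10), 0)
  full <- make_fiber_set(1, raster = matrix(TRUE, 100, 100),
                         image_size = c(100L, 100L))
  expect_equal(box_density(full, box_px = 10), 1)
  # one horizontal centerline through a 100 x 100 image, boxes of 10:
  # 10 boxes at density 10/100, 90 empty -> 0.01
  r <- matrix(FALSE, 100, 100); r[50, ] <- TRUE
  line <- make_fiber_set(1, raster = r, image_size = c(100L, 100L))
  expect_equal(box_density(line, box_px = 10), 0.01)
  expect_warning(bd <- box_density(line, box_px = 200), "single box")
  expect_equal(bd, mean(r))
  expect_error(box_density(line, box_px = 1), ">= 2")
})

test_that("localized density reflects the neighborhood of the centerlines", {
  r <- matrix(FALSE, 100, 100); r[50, ] <- TRUE
  line <- make_fiber_set(1, raster = r, image_size = c(100L, 100L))
  ld <- localized_density(line, window_px = 10)
  # an 11-row window centered on the line holds one full row of pixels
  expect_equal(ld, 1 / 11, tolerance = 0.01)
  expect_equal(localized_density(make_fiber_set(numeric(0))), 0)
})

test_that("extracted fiber angles reproduce the ground-truth alignment", {
  g <- gen_fiber_image(fiber_sim_params(n_fibers = 25, kappa = 2,
                                        placement = "nonoverlap",
                                        image_size_px = c(360L, 360L), seed = 21))
  fs <- extract_fibers(g$image)
  expect_gt(fs$n_fibers, 15)
  ang <- vapply(fs$fibers, `[[`, numeric(1), "angle")
  mvl_rec <- sqrt(mean(cos(2 * ang))^2 + mean(sin(2 * ang))^2)
  expect_lt(abs(mvl_rec - g$truth$mvl_true), 0.1)
})
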