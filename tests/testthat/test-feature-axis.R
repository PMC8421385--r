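synthetic_sample <- function(seed, n_fibers = 30, kappa = 2) {
  g <- gen_fiber_image(fiber_sim_params(image_size_px = c(128L, 128L),
                                        n_fibers = n_fibers, kappa = kappa,
                                        seed = seed))
  field <- subregion_orientations(g$image)
  list(alignment = alignment_summary(field),
       fibers = fiber_metrics(extract_fibers(g$image)),
       group = if (seed %% 2 == 0) "A" else "B")
}

test_that("panel assembly produces the schema shape and flags problems", {
  per_sample <- setNames(lapply(1:4, synthetic_sample), paste0("s", 1:4))
  pan <- assemble_panel(per_sample)
  expect_s3_class(pan, "feature_panel")
  expect_equal(dim(pan), c(4L, 26L))
  expect_identical(names(pan)[-(1:2)], default_feature_schema())
  expect_true(all(is.finite(as.matrix(pan[, -(1:2)]))))
  # a missing feature names the sample and the feature
  broken <- per_sample
  broken$s2$fibers$box_density <- NA_real_
  expect_error(assemble_panel(broken), "sample 's2' feature 'box_density'")
  # ... unless imputation is configured
  pan2 <- assemble_panel(broken, impute = "median")
  expect_true(is.finite(pan2$box_density[pan2$sample == "s2"]))
  # single-feature schema degenerates gracefully
  pan1 <- assemble_panel(per_sample, schema = "mvl")
  expect_equal(ncol(pan1), 3L)
  ax1 <- fit_pca_axis(pan1)
  expect_equal(ax1$variance_explained, 1)
})

test_that("PCA axis satisfies the orthonormality and variance contracts", {
  pan <- gen_feature_panel(c(W = 9, W_H = 9, W_HF = 7, UW = 6), seed = 17)
  ax <- fit_pca_axis(pan)
  L <- ax$loadings
  expect_equal(t(L) %*% L, diag(ncol(L)), tolerance = 1e-8,
               ignore_attr = TRUE)
  ve <- ax$variance_explained
  expect_true(all(diff(ve) <= 1e-12))
  expect_equal(sum(ve), 1, tolerance = 1e-10)
  expect_true(all(ve >= 0 & ve <= 1))
  expect_gte(ax$loadings["mvl", 1], 0)  # fibrosis-positive sign convention
})

test_that("zero-variance features are an error, not a silent drop", {
  pan <- expect_warning(gen_feature_panel(c(A = 5, B = 5), group_sds = 1e-300,
                                          n_features = 3, seed = 1),
                        NA)  # generation itself is fine
  pan$f1 <- 1  # constant column
  expect_error(fit_pca_axis(pan), "zero-variance.*f1")
  flat <- gen_feature_panel(c(A = 3, B = 3), n_features = 2, seed = 2)
  flat$f1 <- 2; flat$f2 <- 5  # panel equal to its mean row repeated
  expect_error(fit_pca_axis(flat), "zero-variance")
  one <- gen_feature_panel(c(A = 1), n_features = 2, seed = 3)
  expect_error(fit_pca_axis(one), "at least 2 samples")
})

test_that("axis is invariant to feature order and affine feature rescaling", {
  pan <- gen_feature_panel(c(A = 10, B = 10), seed = 23)
  ax <- fit_pca_axis(pan)
  feats <- default_feature_schema()
  shuffled <- pan[, c("sample", "group", rev(feats))]
  class(shuffled) <- class(pan)
  ax2 <- fit_pca_axis(shuffled)
  expect_equal(abs(ax2$scores[, 1]), abs(ax$scores[, 1]), tolerance = 1e-8)
  rescaled <- pan
  rescaled$length_mean <- 100 * rescaled$length_mean - 7
  ax3 <- fit_pca_axis(rescaled)
  expect_equal(ax3$scores[, 1], ax$scores[, 1], tolerance = 1e-8)
})

test_that("projection uses the stored axis moments", {
  pan <- gen_planted_panel(seed = 9)
  ax <- fit_pca_axis(pan)
  expect_equal(project_panel(pan, ax), ax$scores, tolerance = 1e-10)
  # the per-feature center projects to the origin
  ctr <- as.data.frame(as.list(ax$center), check.names = FALSE)
  ctr <- cbind(sample = "c", group = "c", ctr)
  class(ctr) <- c("feature_panel", "data.frame")
  expect_equal(as.numeric(project_panel(ctr, ax)), rep(0, ncol(ax$scores)),
               tolerance = 1e-10)
  # held-out fibrotic samples land on the fibrotic side
  held <- gen_planted_panel(seed = 1009)
  sc <- project_panel(held, ax)
  expect_gt(mean(sign(sc[held$group == "fibrotic", 1])), 0.8)
  bad <- pan
  names(bad)[3] <- "not_a_feature"
  expect_error(project_panel(bad, ax), "match")
})

test_that("planted separation is recovered and null panels sit at chance", {
  accs <- vapply(1:30, function(s) {
    pan <- gen_planted_panel(seed = s)
    ax <- fit_pca_axis(pan)
    mean((ax$scores[, 1] > 0) == (pan$group == "fibrotic"))
  }, numeric(1))
  expect_gte(mean(accs), 0.95)
  nulls <- vapply(1:30, function(s) {
    pan <- gen_planted_panel(shift_sd = 0, seed = 5000 + s)
    ax <- fit_pca_axis(pan)
    mean((ax$scores[, 1] > 0) == (pan$group == "fibrotic"))
  }, numeric(1))
  expect_lt(abs(mean(nulls) - 0.5), 3 * sd(nulls) / sqrt(length(nulls)) + 0.02)
})

test_that("panel and axis round-trip through CSV and JSON", {
  pan <- gen_feature_panel(c(A = 5, B = 5), seed = 31)
  f <- withr::local_tempfile(fileext = ".csv")
  write_panel_csv(pan, f)
  pan2 <- read_panel_csv(f)
  expect_equal(as.matrix(pan2[, -(1:2)]), as.matrix(pan[, -(1:2)]),
               tolerance = 1e-12, ignore_attr = TRUE)
  ax <- fit_pca_axis(pan)
  j <- withr::local_tempfile(fileext = ".json")
  write_axis_json(ax, j)
  ax2 <- read_axis_json(j)
  expect_equal(ax2$loadings, ax$loadings, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(project_panel(pan, ax2), ax$scores, tolerance = 1e-8,
               ignore_attr = TRUE)
})
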