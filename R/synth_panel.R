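#' Default collagen-architecture feature schema
#'
#' The 24 per-sample features assembled from the orientation and per-fiber
#' analyses: seven orientation-field statistics and seventeen fiber
#' morphometrics. The schema is configurable everywhere it is consumed; this
#' default is documented in the methods vignette.
#'
#' @return character vector of 24 feature names.
#' @export
default_feature_schema <- function() {
  c("mvl", "mvl_weighted", "circ_sd", "angle_kurtosis", "angle_skewness",
    "angle_entropy", "angle_peak_fraction",
    "n_fibers", "feature_number", "length_mean", "length_sd", "length_median",
    "length_max", "length_cv", "width_mean", "width_sd",
    "straightness_mean", "straightness_sd", "fiber_mvl",
    "fiber_angle_kurtosis", "box_density", "localized_density",
    "total_length_density", "aspect_ratio_mean")
}

#' Simulate a multi-group per-sample feature panel
#'
#' Draws independent Gaussian features per sample with group-specific means,
#' producing a sample x feature table with group labels attached — a
#' stand-in for a measured collagen-architecture panel with planted,
#' known group effects.
#'
#' @param n_per_group integer vector of group sizes (named, or names supplied
#'   via `group_names`).
#' @param group_means numeric matrix `length(n_per_group)` x `n_features` of
#'   per-group feature means, or a single number recycled.
#' @param group_sds per-feature sds (> 0), recycled across features; or a
#'   matrix matching `group_means`.
#' @param n_features number of features.
#' @param feature_names feature names; defaults to [default_feature_schema()]
#'   when `n_features` is 24, else `f1..fk`.
#' @param group_names group labels.
#' @param seed integer seed.
#' @return a `feature_panel` data.frame: columns `sample`, `group`, then one
#'   column per feature.
#' @export
gen_feature_panel <- function(n_per_group = c(W = 9, W_H = 9, W_HF = 7, UW = 6),
                              group_means = 0, group_sds = 1,
                              n_features = 24,
                              feature_names = NULL,
                              group_names = names(n_per_group),
                              seed = 1L) {
  g <- length(n_per_group)
  if (g < 1L || any(n_per_group < 1)) stopf("`n_per_group` must be positive counts")
  if (is.null(group_names)) group_names <- paste0("G", seq_len(g))
  M <- if (is.matrix(group_means)) group_means else
    matrix(group_means, g, n_features)
  S <- if (is.matrix(group_sds)) group_sds else matrix(group_sds, g, n_features)
  if (!identical(dim(M), c(g, as.integer(n_features))) ||
      !identical(dim(S), dim(M)))
    stopf("`group_means`/`group_sds` must be %d x %d", g, n_features)
  if (any(S <= 0)) stopf("all `group_sds` must be > 0")
  if (is.null(feature_names))
    feature_names <- if (n_features == 24) default_feature_schema()
                     else paste0("f", seq_len(n_features))
  if (length(feature_names) != n_features || anyDuplicated(feature_names))
    stopf("`feature_names` must be %d unique names", n_features)
  with_seed(seed, {
    rows <- lapply(seq_len(g), function(i) {
      vals <- matrix(stats::rnorm(n_per_group[i] * n_features), n_per_group[i]) *
        matrix(S[i, ], n_per_group[i], n_features, byrow = TRUE) +
        matrix(M[i, ], n_per_group[i], n_features, byrow = TRUE)
      colnames(vals) <- feature_names
      data.frame(group = group_names[i], vals, check.names = FALSE)
    })
    out <- do.call(rbind, rows)
    out <- data.frame(sample = sprintf("S%02d", seq_len(nrow(out))), out,
                      check.names = FALSE)
    class(out) <- c("feature_panel", "data.frame")
    rownames(out) <- NULL
    out
  })
}

#' Simulate a two-group panel with a planted fibrotic shift
#'
#' Convenience wrapper around [gen_feature_panel()]: a "fibrotic" and a
#' "regenerative" group, with the fibrotic group shifted upward by
#' `shift_sd` standard deviations in `shift_features`. The shifted features
#' include `mvl` by default so the fibrosis-positive sign convention of
#' [fit_pca_axis()] orients PC1 deterministically.
#'
#' The default of 25 samples per group is a power choice: after unit-variance
#' scaling, a block of `k` strongly shifted features contributes a correlation
#' eigenvalue of about `1 + (k - 1)`, which must exceed the
#' Marchenko-Pastur noise edge `(1 + sqrt(p / n))^2` for PC1 to lock onto the
#' planted axis; with `p = 24` features and `k = 3` that requires on the
#' order of 50 samples in total.
#'
#' @param n_per_group two group sizes.
#' @param shift_sd size of the planted shift in sd units (0 = null panel).
#' @param shift_features names of shifted features.
#' @param n_features panel width.
#' @param seed integer seed.
#' @return a `feature_panel` with groups `fibrotic` and `regenerative`.
#' @export
gen_planted_panel <- function(n_per_group = c(fibrotic = 25, regenerative = 25),
                              shift_sd = 10,
                              shift_features = c("mvl", "length_mean", "box_density"),
                              n_features = 24, seed = 1L) {
  feats <- if (n_features == 24) default_feature_schema() else paste0("f", seq_len(n_features))
  if (!all(shift_features %in% feats))
    stopf("shift_features must be drawn from the panel schema")
  M <- matrix(0, 2, n_features, dimnames = list(NULL, feats))
  M[1, shift_features] <- shift_sd
  gen_feature_panel(n_per_group, group_means = M, group_sds = 1,
                    n_features = n_features, feature_names = feats, seed = seed)
}
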