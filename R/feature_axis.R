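#' Assemble the per-sample collagen-architecture feature panel
#'
#' Builds one row per sample from that sample's orientation-field summary and
#' fiber-metrics summary, following an ordered feature schema (default: the 24
#' features of [default_feature_schema()]). Every sample must supply every
#' schema feature as a finite value unless an imputation policy is given.
#'
#' @param per_sample named list; each element is a list with components
#'   `alignment` (an `alignment_summary`), `fibers` (a
#'   `fiber_metrics_summary`) and `group` (label).
#' @param schema ordered character vector of feature names.
#' @param impute `NULL` (missing features are an error naming sample and
#'   feature), or `"median"` to replace missing values with the per-feature
#'   median across samples.
#' @return a `feature_panel` data.frame: `sample`, `group`, then the schema
#'   columns. A warning names any zero-variance feature columns.
#' @export
assemble_panel <- function(per_sample, schema = default_feature_schema(),
                           impute = NULL) {
  if (!length(per_sample)) stopf("`per_sample` is empty")
  if (!length(schema)) stopf("`schema` must name at least one feature")
  if (anyDuplicated(schema)) stopf("feature names in `schema` must be unique")
  ids <- names(per_sample) %||% sprintf("S%02d", seq_along(per_sample))
  rows <- lapply(seq_along(per_sample), function(i) {
    s <- per_sample[[i]]
    vals <- sample_features(s$alignment, s$fibers)
    out <- vals[schema]
    names(out) <- schema
    out
  })
  M <- do.call(rbind, rows)
  bad <- which(!is.finite(M), arr.ind = TRUE)
  if (nrow(bad)) {
    if (is.null(impute)) {
      stopf("missing feature value(s): %s",
            paste(sprintf("sample '%s' feature '%s'",
                          ids[bad[, 1]], schema[bad[, 2]]), collapse = "; "))
    } else if (impute == "median") {
      for (j in unique(bad[, 2])) {
        med <- stats::median(M[, j], na.rm = TRUE)
        if (!is.finite(med)) stopf("feature '%s' has no finite values to impute from", schema[j])
        M[!is.finite(M[, j]), j] <- med
      }
    } else stopf("unknown imputation policy '%s'", impute)
  }
  if (nrow(M) > 1L) {
    sds <- apply(M, 2, stats::sd)
    if (any(sds == 0))
      warnf("zero-variance feature column(s): %s",
            paste(schema[sds == 0], collapse = ", "))
  }
  groups <- vapply(per_sample, function(s) as.character(s$group %||% NA_character_),
                   character(1))
  out <- data.frame(sample = ids, group = groups, M, check.names = FALSE)
  rownames(out) <- NULL
  class(out) <- c("feature_panel", "data.frame")
  out
}

# map the two per-sample summaries onto the named feature vocabulary
sample_features <- function(alignment, fibers) {
  a <- alignment; f <- fibers
  c(mvl = a$mvl_unit %||% a$mvl,
    mvl_weighted = a$mvl_weighted %||% NA_real_,
    circ_sd = a$circ_sd %||% NA_real_,
    angle_kurtosis = a$angle_kurtosis %||% NA_real_,
    angle_skewness = a$angle_skewness %||% NA_real_,
    angle_entropy = a$angle_entropy %||% NA_real_,
    angle_peak_fraction = a$angle_peak_fraction %||% NA_real_,
    n_fibers = f$n_fibers %||% NA_real_,
    feature_number = f$feature_number %||% NA_real_,
    length_mean = f$length_mean %||% NA_real_,
    length_sd = f$length_sd %||% NA_real_,
    length_median = f$length_median %||% NA_real_,
    length_max = f$length_max %||% NA_real_,
    length_cv = f$length_cv %||% NA_real_,
    width_mean = f$width_mean %||% NA_real_,
    width_sd = f$width_sd %||% NA_real_,
    straightness_mean = f$straightness_mean %||% NA_real_,
    straightness_sd = f$straightness_sd %||% NA_real_,
    fiber_mvl = f$fiber_mvl %||% NA_real_,
    fiber_angle_kurtosis = f$fiber_angle_kurtosis %||% NA_real_,
    box_density = f$box_density %||% NA_real_,
    localized_density = f$localized_density %||% NA_real_,
    total_length_density = f$total_length_density %||% NA_real_,
    aspect_ratio_mean = f$aspect_ratio_mean %||% NA_real_)
}

panel_matrix <- function(panel) {
  feats <- setdiff(names(panel), c("sample", "group"))
  M <- as.matrix(panel[, feats, drop = FALSE])
  rownames(M) <- panel$sample
  M
}

#' Fit the PCA fibrosis-regeneration axis
#'
#' Principal component analysis of the feature panel with centering to mean
#' zero and scaling to unit variance. The sign of PC1 is fixed so that the
#' loading of `sign_feature` (default `mvl`, the alignment statistic that
#' increases with fibrosis) is positive, making the fibrotic direction of the
#' axis deterministic.
#'
#' @param panel a `feature_panel`.
#' @param sign_feature feature anchoring the PC1 sign; ignored with a warning
#'   if absent from the panel.
#' @return an `axis_model`: `loadings` (features x components), `center`,
#'   `scale`, `variance_explained`, `scores` (samples x components),
#'   `features`, `samples`, `groups`.
#' @export
fit_pca_axis <- function(panel, sign_feature = "mvl") {
  M <- panel_matrix(panel)
  if (nrow(M) < 2L) stopf("PCA needs at least 2 samples")
  sds <- apply(M, 2, stats::sd)
  if (any(sds == 0))
    stopf("zero-variance feature(s) cannot be scaled to unit variance: %s (remove them or jitter the panel)",
          paste(colnames(M)[sds == 0], collapse = ", "))
  pc <- stats::prcomp(M, center = TRUE, scale. = TRUE)
  if (sign_feature %in% colnames(M)) {
    if (pc$rotation[sign_feature, 1] < 0) {
      pc$rotation[, 1] <- -pc$rotation[, 1]
      pc$x[, 1] <- -pc$x[, 1]
    }
  } else warnf("sign feature '%s' not in panel; PC1 sign left as computed", sign_feature)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(loadings = pc$rotation,
                 center = pc$center, scale = pc$scale,
                 variance_explained = ve,
                 scores = pc$x,
                 features = colnames(M),
                 samples = panel$sample,
                 groups = panel$group), class = "axis_model")
}

#' @export
print.axis_model <- function(x, ...) {
  ve <- x$variance_explained
  cat(sprintf("<axis_model> %d features, %d samples; PC1 %.1f%%, PC2 %.1f%%, PC3 %.1f%% of variance\n",
              length(x$features), nrow(x$scores),
              100 * ve[1], 100 * (ve[2] %||% NA), 100 * (ve[3] %||% NA)))
  invisible(x)
}

#' Project a feature panel onto a fitted axis
#'
#' Applies the stored centering and scaling of the axis (not the new panel's
#' own moments) and multiplies by the loadings, so held-out samples are
#' scored on the training axis.
#'
#' @param panel a `feature_panel` whose feature columns match the axis.
#' @param axis an `axis_model` from [fit_pca_axis()].
#' @return samples x components score matrix.
#' @export
project_panel <- function(panel, axis) {
  M <- panel_matrix(panel)
  if (!identical(sort(colnames(M)), sort(axis$features)))
    stopf("panel features do not match the axis features")
  M <- M[, axis$features, drop = FALSE]
  scale(M, center = axis$center, scale = axis$scale) %*% axis$loadings
}

#' Write / read an axis model as JSON
#'
#' @param axis an `axis_model`.
#' @param path JSON path.
#' @return `write_axis_json` returns `path` invisibly; `read_axis_json`
#'   returns an `axis_model` (without scores).
#' @export
write_axis_json <- function(axis, path) {
  jsonlite::write_json(list(
    features = axis$features,
    center = as.list(axis$center), scale = as.list(axis$scale),
    variance_explained = axis$variance_explained,
    loadings = apply(axis$loadings, 2, identity, simplify = FALSE)),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_axis_json
#' @export
read_axis_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  L <- do.call(cbind, lapply(j$loadings, unlist))
  rownames(L) <- j$features
  structure(list(loadings = L,
                 center = unlist(j$center), scale = unlist(j$scale),
                 variance_explained = unlist(j$variance_explained),
                 scores = NULL, features = j$features,
                 samples = NULL, groups = NULL), class = "axis_model")
}

#' Write a feature panel to CSV
#'
#' Header row `sample, group, <features>`; [read_panel_csv()] restores the
#' `feature_panel` class.
#'
#' @param panel a `feature_panel`.
#' @param path CSV path.
#' @return `path` invisibly / a `feature_panel`.
#' @export
write_panel_csv <- function(panel, path) {
  utils::write.csv(panel, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel_csv
#' @export
read_panel_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("sample", "group") %in% names(df)))
    stopf("panel CSV must start with columns sample, group")
  class(df) <- c("feature_panel", "data.frame")
  df
}
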