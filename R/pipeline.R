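#' Validate a pipeline configuration
#'
#' Checks a configuration (a list, or a path to a YAML file) for the
#' architecture pipeline: manifest presence and columns, resolvability of all
#' referenced image/mask paths, known schema features, and parameter ranges.
#'
#' @param config list or YAML file path.
#' @return character vector of human-readable diagnostics; empty when valid.
#' @export
validate_config <- function(config) {
  diag <- character(0)
  if (is.character(config)) {
    if (!file.exists(config)) return(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) return("config must be a list or a YAML file path")
  man <- config$manifest
  if (is.null(man)) {
    diag <- c(diag, "missing `manifest`")
  } else {
    if (is.character(man)) {
      if (!file.exists(man)) {
        diag <- c(diag, sprintf("manifest file not found: %s", man))
        man <- NULL
      } else man <- utils::read.csv(man)
    }
    if (!is.null(man)) {
      need <- c("sample", "group", "image")
      missing_cols <- setdiff(need, names(man))
      if (length(missing_cols))
        diag <- c(diag, sprintf("manifest lacks column(s): %s",
                                paste(missing_cols, collapse = ", ")))
      if ("image" %in% names(man))
        for (p in man$image) if (!file.exists(p))
          diag <- c(diag, sprintf("image path not found: %s", p))
      if ("mask" %in% names(man))
        for (p in stats::na.omit(man$mask)) if (nzchar(p) && !file.exists(p))
          diag <- c(diag, sprintf("mask path not found: %s", p))
    }
  }
  schema <- config$schema %||% default_feature_schema()
  unknown <- setdiff(schema, default_feature_schema())
  if (length(unknown))
    diag <- c(diag, sprintf("unknown feature(s) in schema: %s",
                            paste(unknown, collapse = ", ")))
  if (!length(schema)) diag <- c(diag, "schema is empty")
  sp <- config$orientation$subregion_px %||% 5
  if (sp < 3) diag <- c(diag, "orientation.subregion_px must be >= 3")
  q <- config$orientation$weight_cutoff_quantile %||% 0.25
  if (q < 0 || q > 1) diag <- c(diag, "orientation.weight_cutoff_quantile must be in [0, 1]")
  ml <- config$fibers$min_fiber_len_px %||% 10
  if (ml < 2) diag <- c(diag, "fibers.min_fiber_len_px must be >= 2")
  diag
}

#' Run the full collagen-architecture pipeline
#'
#' Orchestrates, for every sample in the manifest: image reading, orientation
#' field + alignment summary, fiber extraction + morphometrics, panel
#' assembly, PCA axis fitting, and one-way group statistics on the PC1
#' scores. Per-sample failures are recorded and do not abort the remaining
#' samples. All outputs (panel CSV, axis JSON, score CSV, stats CSV, and a
#' run log listing every resolved parameter) are written under
#' `config$output_dir` when given. Deterministic for a fixed config and seed.
#'
#' @param config list or YAML path; see [validate_config()] for the contract.
#'   Keys: `manifest` (data.frame or CSV with `sample`, `group`, `image`,
#'   optional `mask`), `orientation` (subregion_px, gradient_operator,
#'   weight_cutoff_quantile, weighted), `fibers` (smooth_sigma,
#'   threshold_method, min_fiber_len_px, box_px), `schema`, `pca`
#'   (sign_feature), `stats` (test), `output_dir`, `seed`.
#' @return list with `panel`, `axis` (NULL if < 2 usable samples), `stats`
#'   (NULL if < 2 groups), `failures` (named character vector of per-sample
#'   error messages), and `exit_status` (0 success, 1 partial failure,
#'   2 config error — also returned, not just raised, for scripting).
#' @export
run_architecture_pipeline <- function(config) {
  diag <- validate_config(config)
  if (length(diag)) {
    warnf("invalid config:\n%s", paste(" -", diag, collapse = "\n"))
    return(list(panel = NULL, axis = NULL, stats = NULL,
                failures = diag, exit_status = 2L))
  }
  if (is.character(config)) config <- yaml::read_yaml(config)
  man <- config$manifest
  if (is.character(man)) man <- utils::read.csv(man)
  ocfg <- config$orientation %||% list()
  fcfg <- config$fibers %||% list()
  schema <- config$schema %||% default_feature_schema()
  sign_feature <- config$pca$sign_feature %||% "mvl"
  test <- config$stats$test %||% "anova_tukey"
  outdir <- config$output_dir
  seed <- config$seed %||% 1L

  resolved <- list(
    orientation = list(subregion_px = ocfg$subregion_px %||% 5L,
                       gradient_operator = ocfg$gradient_operator %||% "sobel",
                       weight_cutoff_quantile = ocfg$weight_cutoff_quantile %||% 0.25,
                       weighted = isTRUE(ocfg$weighted)),
    fibers = list(smooth_sigma = fcfg$smooth_sigma %||% 1,
                  threshold_method = fcfg$threshold_method %||% "otsu",
                  min_fiber_len_px = fcfg$min_fiber_len_px %||% 10,
                  box_px = fcfg$box_px %||% 32L),
    schema = schema, sign_feature = sign_feature, test = test, seed = seed)

  failures <- character(0)
  per_sample <- list()
  for (i in seq_len(nrow(man))) {
    sid <- as.character(man$sample[i])
    res <- tryCatch({
      img <- read_image(man$image[i])
      if (!is.null(man$mask) && !is.na(man$mask[i]) && nzchar(man$mask[i]))
        img$mask <- read_image(man$mask[i])$pixels > 0.5
      field <- subregion_orientations(
        img, subregion_px = resolved$orientation$subregion_px,
        gradient_operator = resolved$orientation$gradient_operator,
        weight_cutoff_quantile = resolved$orientation$weight_cutoff_quantile)
      al <- alignment_summary(field, weighted = resolved$orientation$weighted)
      fs <- extract_fibers(img,
                           smooth_sigma = resolved$fibers$smooth_sigma,
                           threshold_method = resolved$fibers$threshold_method,
                           min_fiber_len_px = resolved$fibers$min_fiber_len_px)
      fm <- fiber_metrics(fs, box_px = resolved$fibers$box_px)
      list(alignment = al, fibers = fm, group = as.character(man$group[i]))
    }, error = function(e) e)
    if (inherits(res, "error")) failures[sid] <- conditionMessage(res)
    else per_sample[[sid]] <- res
  }

  panel <- axis <- stats_rep <- NULL
  if (length(per_sample))
    panel <- assemble_panel(per_sample, schema = schema)
  if (!is.null(panel) && nrow(panel) >= 2L) {
    axis <- tryCatch(fit_pca_axis(panel, sign_feature = sign_feature),
                     error = function(e) { failures["pca"] <<- conditionMessage(e); NULL })
  }
  if (!is.null(axis)) {
    if (length(unique(panel$group)) >= 2L && all(table(panel$group) >= 2)) {
      stats_rep <- compare_groups(axis$scores[, 1], panel$group,
                                  test = test, metric = "PC1")
    } else warnf("fewer than 2 replicated groups; statistics stage skipped")
  }

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(panel)) write_panel_csv(panel, file.path(outdir, "feature_panel.csv"))
    if (!is.null(axis)) {
      write_axis_json(axis, file.path(outdir, "axis_model.json"))
      utils::write.csv(data.frame(sample = axis$samples, group = axis$groups,
                                  axis$scores, check.names = FALSE),
                       file.path(outdir, "pc_scores.csv"), row.names = FALSE)
    }
    if (!is.null(stats_rep)) write_stats_csv(stats_rep, file.path(outdir, "stats_report.csv"))
    log <- c(sprintf("fiberarch %s", as.character(utils::packageVersion("fiberarch"))),
             sprintf("run at %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
             sprintf("samples: %d processed, %d failed", length(per_sample), length(failures)),
             "resolved parameters:",
             utils::capture.output(utils::str(resolved)),
             if (length(failures)) c("failures:", paste(" -", names(failures), ":", failures)))
    writeLines(log, file.path(outdir, "run_log.txt"))
  }
  list(panel = panel, axis = axis, stats = stats_rep, failures = failures,
       exit_status = if (length(failures)) 1L else 0L)
}
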