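#' Group comparison report for a derived metric
#'
#' Reporting layer over the standard tests used for per-sample metrics:
#' one-way ANOVA with Tukey's multiple-comparisons test, two-way ANOVA with a
#' second factor, or unpaired/paired Student's t-tests. Group summaries are
#' means with SEM (sample sd / sqrt(n)); comparisons are flagged significant
#' at `alpha` (default 0.05).
#'
#' @param values numeric per-sample metric.
#' @param group factor (or coercible) of group labels, >= 2 levels, each with
#'   >= 2 observations.
#' @param test one of `"anova_tukey"`, `"anova2_tukey"`, `"t_unpaired"`,
#'   `"t_paired"`.
#' @param second_factor second design factor, required for `anova2_tukey`.
#' @param pairing sample pairing key, required for `t_paired`; must pair each
#'   observation in one group with exactly one in the other.
#' @param metric metric name carried into the report rows.
#' @param alpha significance level.
#' @return a `stats_report`: `summary` (metric, group, n, mean, sem) and
#'   `tests` (comparison, test, statistic, p, p_adj, significant).
#' @export
compare_groups <- function(values, group,
                           test = c("anova_tukey", "anova2_tukey",
                                    "t_unpaired", "t_paired"),
                           second_factor = NULL, pairing = NULL,
                           metric = "value", alpha = 0.05) {
  test <- match.arg(test)
  group <- factor(group)
  if (length(values) != length(group)) stopf("`values` and `group` lengths differ")
  if (nlevels(group) < 2L) stopf("need at least 2 groups")
  ns <- table(group)
  if (any(ns < 2L))
    stopf("insufficient replication (n < 2) in group(s): %s",
          paste(names(ns)[ns < 2], collapse = ", "))
  if (test %in% c("t_unpaired", "t_paired") && nlevels(group) != 2L)
    stopf("t-tests require exactly 2 groups")

  summary_df <- do.call(rbind, lapply(levels(group), function(g) {
    v <- values[group == g]
    data.frame(metric = metric, group = g, n = length(v),
               mean = mean(v), sem = stats::sd(v) / sqrt(length(v)))
  }))

  tests_df <- switch(test,
    anova_tukey = {
      fit <- stats::aov(values ~ group)
      an <- summary(fit)[[1]]
      tk <- stats::TukeyHSD(fit)$group
      pw_unadj <- pairwise_p_pooled(values, group, fit)
      rbind(
        data.frame(comparison = "overall", test = "one-way ANOVA",
                   statistic = an$`F value`[1], p = an$`Pr(>F)`[1],
                   p_adj = NA_real_,
                   significant = an$`Pr(>F)`[1] < alpha),
        data.frame(comparison = rownames(tk), test = "Tukey HSD",
                   statistic = tk[, "diff"],
                   p = pw_unadj[rownames(tk)],
                   p_adj = tk[, "p adj"],
                   significant = tk[, "p adj"] < alpha))
    },
    anova2_tukey = {
      if (is.null(second_factor)) stopf("`second_factor` is required for two-way ANOVA")
      f2 <- factor(second_factor)
      if (length(f2) != length(values)) stopf("`second_factor` length differs from `values`")
      fit <- stats::aov(values ~ group * f2)
      an <- summary(fit)[[1]]
      tk <- stats::TukeyHSD(fit, which = "group")$group
      terms <- trimws(rownames(an))
      keep <- terms != "Residuals"
      rbind(
        data.frame(comparison = terms[keep], test = "two-way ANOVA",
                   statistic = an$`F value`[keep], p = an$`Pr(>F)`[keep],
                   p_adj = NA_real_, significant = an$`Pr(>F)`[keep] < alpha),
        data.frame(comparison = rownames(tk), test = "Tukey HSD",
                   statistic = tk[, "diff"], p = NA_real_,
                   p_adj = tk[, "p adj"], significant = tk[, "p adj"] < alpha))
    },
    t_unpaired = {
      tt <- stats::t.test(values ~ group, var.equal = TRUE)
      data.frame(comparison = paste(levels(group), collapse = " vs "),
                 test = "unpaired t", statistic = unname(tt$statistic),
                 p = tt$p.value, p_adj = NA_real_,
                 significant = tt$p.value < alpha)
    },
    t_paired = {
      if (is.null(pairing)) stopf("`pairing` is required for a paired t-test")
      g1 <- levels(group)[1]; g2 <- levels(group)[2]
      k1 <- pairing[group == g1]; k2 <- pairing[group == g2]
      if (anyDuplicated(k1) || anyDuplicated(k2) ||
          !setequal(k1, k2) || length(k1) != length(k2))
        stopf("`pairing` must match each observation in '%s' to exactly one in '%s'", g1, g2)
      v1 <- values[group == g1][order(k1)]
      v2 <- values[group == g2][order(k2)]
      d <- v1 - v2
      if (stats::sd(d) == 0 && mean(d) == 0) {
        # identical pairs: t = 0, p = 1 by convention
        data.frame(comparison = paste(g1, "vs", g2), test = "paired t",
                   statistic = 0, p = 1, p_adj = NA_real_, significant = FALSE)
      } else {
        tt <- stats::t.test(v1, v2, paired = TRUE)
        data.frame(comparison = paste(g1, "vs", g2), test = "paired t",
                   statistic = unname(tt$statistic), p = tt$p.value,
                   p_adj = NA_real_, significant = tt$p.value < alpha)
      }
    })
  rownames(tests_df) <- NULL
  structure(list(summary = summary_df, tests = tests_df,
                 metric = metric, alpha = alpha, test = test),
            class = "stats_report")
}

# unadjusted pairwise p-values from the pooled ANOVA error term, keyed
# "B-A" like TukeyHSD rows, so the Tukey adjustment is directly comparable
pairwise_p_pooled <- function(values, group, fit) {
  lv <- levels(group)
  df_res <- fit$df.residual
  mse <- sum(stats::residuals(fit)^2) / df_res
  out <- c()
  for (i in seq_along(lv)) for (j in seq_len(i - 1)) {
    vi <- values[group == lv[i]]; vj <- values[group == lv[j]]
    se <- sqrt(mse * (1 / length(vi) + 1 / length(vj)))
    tstat <- (mean(vi) - mean(vj)) / se
    out[paste0(lv[i], "-", lv[j])] <- 2 * stats::pt(-abs(tstat), df_res)
  }
  out
}

#' @export
print.stats_report <- function(x, ...) {
  cat(sprintf("<stats_report> metric '%s', %s (alpha = %g)\n",
              x$metric, x$test, x$alpha))
  print(x$summary, row.names = FALSE)
  print(x$tests, row.names = FALSE)
  invisible(x)
}

#' Write a stats report to CSV
#'
#' Each row carries metric, comparison, per-group n/mean/SEM context,
#' statistic, p, adjusted p.
#'
#' @param report a `stats_report`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_stats_csv <- function(report, path) {
  utils::write.csv(merge_report(report), path, row.names = FALSE)
  invisible(path)
}

merge_report <- function(report) {
  s <- report$summary
  groups_str <- paste(sprintf("%s: n=%d, %.4g +/- %.4g", s$group, s$n, s$mean, s$sem),
                      collapse = "; ")
  cbind(report$tests, metric = report$metric, group_summaries = groups_str)
}
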