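# Nonparametric group comparisons of LOI features.
#
# The analysis mirrors the clinical workflow: a normality screen first
# (feature distributions are typically non-normal), then two-sided
# nonparametric tests at alpha = 0.05 per comparison — the two-sample
# Wilcoxon rank-sum for the plateau medians and SDs, and Kruskal-Wallis for
# the gradients. The normality screen only gates reporting; the pipeline
# always proceeds nonparametrically. No multiple-testing correction by
# default (per-comparison reporting); a Holm option is available.

stat_result <- function(test_name, statistic, p_value, n_per_group, alpha,
                        method = NA_character_) {
  structure(list(test_name = test_name, statistic = unname(statistic),
                 p_value = unname(p_value), n_per_group = n_per_group,
                 alpha = alpha, significant = p_value < alpha,
                 method = method),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (%s at alpha = %g)%s\n",
              x$test_name, x$statistic, x$p_value,
              if (x$significant) "significant" else "not significant",
              x$alpha,
              if (!is.na(x$method)) sprintf(" [%s]", x$method) else ""))
  invisible(x)
}

#' Shapiro-Wilk normality screen
#'
#' @param x Numeric sample, `n >= 3` and non-degenerate.
#' @param alpha Significance level; default 0.05.
#' @return A `stat_result` (significant = evidence against normality).
#' @export
normality_test <- function(x, alpha = 0.05) {
  x <- as.numeric(x)
  if (length(x) < 3L) stopf("normality test needs n >= 3 (got %d)", length(x))
  if (stats::sd(x) == 0) stopf("degenerate input: all values identical")
  if (length(x) > 5000L) x <- x[seq(1L, length(x), length.out = 5000L)]
  ht <- stats::shapiro.test(x)
  stat_result("Shapiro-Wilk", ht$statistic, ht$p.value, length(x), alpha)
}

#' Two-sample Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided. Exact enumeration when `n1 + n2 <= 12` and the pooled sample is
#' tie-free; otherwise the tie-corrected normal approximation (no continuity
#' correction, so that the two-group Kruskal-Wallis test is its square).
#'
#' @param group1,group2 Numeric samples, each `n >= 2`.
#' @param alpha Significance level; default 0.05.
#' @return A `stat_result`; `method` records `"exact"` or `"normal-approx"`.
#' @export
rank_sum_test <- function(group1, group2, alpha = 0.05) {
  group1 <- as.numeric(group1); group2 <- as.numeric(group2)
  if (length(group1) < 2L || length(group2) < 2L)
    stopf("rank-sum test needs n >= 2 in both groups")
  n <- length(group1) + length(group2)
  ties <- anyDuplicated(c(group1, group2)) > 0L
  exact <- n <= 12L && !ties
  ht <- suppressWarnings(stats::wilcox.test(group1, group2, exact = exact,
                                            correct = FALSE))
  stat_result("Wilcoxon rank-sum", ht$statistic, ht$p.value,
              c(length(group1), length(group2)), alpha,
              method = if (exact) "exact" else "normal-approx")
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic with a chi-squared reference on k - 1 degrees of
#' freedom.
#'
#' @param groups List of `>= 2` numeric samples, each `n >= 2`.
#' @param alpha Significance level; default 0.05.
#' @return A `stat_result`.
#' @export
kruskal_wallis <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2L)
    stopf("Kruskal-Wallis needs a list of >= 2 groups")
  if (any(vapply(groups, length, 1L) < 2L))
    stopf("each group needs n >= 2")
  ht <- stats::kruskal.test(groups)
  stat_result("Kruskal-Wallis", ht$statistic, ht$p.value,
              vapply(groups, length, 1L), alpha)
}

#' Compare feature distributions between the two lesion classes
#'
#' One row per comparison: the plateau medians (`median_E`, `median_T`) and
#' SDs (`std_E`, `std_T`) via the rank-sum test, and each gradient
#' (`grad_E_rise`, `grad_E_fall`, `grad_T_rise`) via Kruskal-Wallis between
#' the classes. Each row carries the normality screen of the pooled feature.
#'
#' @param cohort A `rel_cohort` or any data frame with `label` plus the
#'   feature columns.
#' @param alpha Significance level; default 0.05.
#' @param p_adjust `"none"` (default, per-comparison reporting) or `"holm"`.
#' @return Data frame with columns `feature`, `test`, `statistic`, `p_value`,
#'   `significant`, `normality_p`, `normal`.
#' @export
compare_cohort <- function(cohort, alpha = 0.05,
                           p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  labs <- unique(cohort$label)
  if (length(labs) < 2L)
    stopf("cohort comparison needs both classes present")
  comparisons <- list(
    median_E = "ranksum", median_T = "ranksum",
    std_E = "ranksum", std_T = "ranksum",
    grad_E_rise = "kruskal", grad_E_fall = "kruskal",
    grad_T_rise = "kruskal")
  rows <- lapply(names(comparisons), function(feat) {
    x <- cohort[[feat]]
    g1 <- x[cohort$label == "GBM"]; g2 <- x[cohort$label == "ABSCESS"]
    res <- if (comparisons[[feat]] == "ranksum") rank_sum_test(g1, g2, alpha)
    else kruskal_wallis(list(GBM = g1, ABSCESS = g2), alpha)
    norm_p <- tryCatch(normality_test(x)$p_value, error = function(e) NA_real_)
    data.frame(feature = feat, test = res$test_name,
               statistic = res$statistic, p_value = res$p_value,
               significant = res$significant, normality_p = norm_p,
               normal = !is.na(norm_p) && norm_p >= alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (p_adjust == "holm") {
    out$p_value <- stats::p.adjust(out$p_value, "holm")
    out$significant <- out$p_value < alpha
  }
  out
}

#' Long-format feature table for boxplots
#'
#' @param cohort A `rel_cohort` or compatible data frame.
#' @param features Feature columns to include; default the seven predictors.
#' @return Long data frame with columns `feature`, `label`, `value`.
#' @export
feature_long <- function(cohort, features = feature_names("seven")) {
  do.call(rbind, lapply(features, function(f)
    data.frame(feature = f, label = cohort$label, value = cohort[[f]],
               stringsAsFactors = FALSE)))
}

#' Boxplots of feature distributions by class
#'
#' @param cohort A `rel_cohort` or compatible data frame.
#' @param features Feature columns to plot.
#' @param ... Passed to [graphics::boxplot()].
#' @export
feature_boxplot <- function(cohort, features = c("median_E", "median_T"),
                            ...) {
  long <- feature_long(cohort, features)
  graphics::boxplot(value ~ interaction(label, feature), data = long,
                    las = 2, ylab = "ADC [paper units]", ...)
  invisible(long)
}
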