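#' @title Statistical kernels: rank-sum and two-sample proportion tests
#' @description
#' Thin, validated surfaces over the same tests the analysis relies on
#' throughout: the Wilcoxon rank-sum test (exact for small tie-free
#' samples, normal approximation with tie correction otherwise) and the
#' chi-square test of equal proportions with optional Yates continuity
#' correction.
#' @name stats_core
NULL

#' Wilcoxon rank-sum test
#'
#' Exact permutation p-value when both samples have at most `exact_max`
#' observations and no ties are present; otherwise the normal approximation
#' with tie correction and continuity correction. Two-sided p-values follow
#' the doubled-tail convention, capped at 1.
#'
#' @param x,y numeric samples (non-empty).
#' @param two_sided two-sided test (default) or greater-tail.
#' @param exact_max largest per-sample size for the exact method.
#' @return list of class `rank_sum_result`: `statistic` (W, the rank-sum
#'   statistic of `x` shifted by its minimum), `p_value`, `method`
#'   (`"exact"` or `"normal-approx"`), `n_x`, `n_y`.
#' @export
wilcoxon_rank_sum <- function(x, y, two_sided = TRUE, exact_max = 20) {
  if (!length(x) || !length(y)) stop("wilcoxon_rank_sum: empty sample")
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- !ties && length(x) <= exact_max && length(y) <= exact_max
  ht <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = if (two_sided) "two.sided" else "greater",
    exact = use_exact, correct = TRUE))
  p <- unname(ht$p.value)
  # fully tied data (zero rank variance): identical distributions
  if (is.nan(p) && length(unique(c(x, y))) == 1) p <- 1
  structure(list(statistic = unname(ht$statistic),
                 p_value = p,
                 method = if (use_exact) "exact" else "normal-approx",
                 n_x = length(x), n_y = length(y)),
            class = "rank_sum_result")
}

#' @export
print.rank_sum_result <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum (%s): W = %.6g, p = %.4g (n = %d, %d)\n",
              x$method, x$statistic, x$p_value, x$n_x, x$n_y))
  invisible(x)
}

#' Two-sample test of equal proportions
#'
#' Chi-square test that two binomial proportions are equal, with the Yates
#' continuity correction on by default (matching `prop.test()` defaults);
#' the corrected p-value is always at least the uncorrected one.
#'
#' @param x1,n1 successes and trials in group 1.
#' @param x2,n2 successes and trials in group 2.
#' @param continuity apply the Yates correction.
#' @return list of class `prop_test_result`: `statistic` (chi-square),
#'   `p_value`, `prop1`, `prop2`, `continuity`.
#' @export
two_sample_proportion_test <- function(x1, n1, x2, n2, continuity = TRUE) {
  if (n1 <= 0 || n2 <= 0) stop("two_sample_proportion_test: zero trials")
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2)
    stop("two_sample_proportion_test: successes outside [0, n]")
  ht <- suppressWarnings(stats::prop.test(c(x1, x2), c(n1, n2),
                                          correct = continuity))
  stat <- unname(ht$statistic)
  p <- unname(ht$p.value)
  # pooled proportion of 0 or 1 leaves the chi-square undefined; it can
  # only arise when both sample proportions are equal
  if (is.nan(stat) || is.nan(p)) { stat <- 0; p <- 1 }
  structure(list(statistic = stat,
                 p_value = p,
                 prop1 = x1 / n1, prop2 = x2 / n2,
                 continuity = continuity),
            class = "prop_test_result")
}

#' @export
print.prop_test_result <- function(x, ...) {
  cat(sprintf(
    "Two-sample proportion test%s: X^2 = %.4f, p = %.4g (%.4f vs %.4f)\n",
    if (x$continuity) " (Yates)" else "", x$statistic, x$p_value,
    x$prop1, x$prop2))
  invisible(x)
}

#' Round half up to a fixed number of decimals
#'
#' Deterministic decimal rounding (0.005 -> 0.01) used for the report
#' percentages and fold changes, avoiding banker's rounding surprises.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

#' Format a count ratio as a percentage string (2 dp, round half up)
#'
#' @param numerator,denominator counts.
#' @param digits decimal places.
#' @return list with `percent` (numeric) and `string` (e.g. "65.58%").
#' @export
format_percent <- function(numerator, denominator, digits = 2) {
  pct <- round_half_up(100 * numerator / denominator, digits)
  list(percent = pct, string = sprintf(paste0("%.", digits, "f%%"), pct))
}
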