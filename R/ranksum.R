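#' Wilcoxon rank-sum test with explicit small-sample handling
#'
#' Exact null distribution when both samples have at most 25 observations
#' and no ties are present; otherwise the normal approximation with tie
#' correction and without continuity correction, so that exchangeable
#' samples give a one-sided p-value of exactly 0.5.
#'
#' @param x,y Numeric samples.
#' @param alternative `"greater"`, `"less"`, or `"two.sided"`; sided
#'   alternatives refer to `x` relative to `y`.
#' @return A list with `statistic` (the W statistic), `p_value`, and
#'   `method` (`"exact"` or `"normal"`).
#' @export
rank_sum_test <- function(x, y, alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  has_ties <- anyDuplicated(c(x, y)) > 0
  exact <- length(x) <= 25 && length(y) <= 25 && !has_ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative, exact = exact,
                       correct = FALSE)
  )
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       method = if (exact) "exact" else "normal")
}
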