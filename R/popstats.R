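#' 'N-1' chi-squared test for two proportions
#'
#' Comparison of two independent proportions with the 'N-1' variant of the
#' Pearson chi-squared test: the usual Pearson statistic of the 2x2 table is
#' rescaled by (N - 1)/N, N = n1 + n2, and referred to the chi-squared
#' distribution with 1 df (two-sided tail). The variant keeps the test close
#' to nominal size at the small-to-moderate sample sizes typical of
#' per-genotype fly counts; no minimum expected-cell rule is applied.
#'
#' @param k1,n1 successes and total in group 1.
#' @param k2,n2 successes and total in group 2.
#' @return list with `statistic`, `p_value`, `estimate` (the two
#'   proportions), and the input counts.
#' @examples
#' n1Chisq(14, 20, 7, 20)
#' @export
n1Chisq <- function(k1, n1, k2, n2) {
  stopIfNot1(n1 >= 1 && n2 >= 1, "group sizes must be >= 1")
  stopIfNot1(k1 >= 0 && k2 >= 0 && k1 <= n1 && k2 <= n2,
             "counts must satisfy 0 <= k <= n")
  N <- n1 + n2
  p <- (k1 + k2) / N
  stat <- if (p == 0 || p == 1) 0 else {
    e <- outer(c(n1, n2), c(p, 1 - p))
    o <- rbind(c(k1, n1 - k1), c(k2, n2 - k2))
    sum((o - e)^2 / e) * (N - 1) / N
  }
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       estimate = c(p1 = k1 / n1, p2 = k2 / n2),
       k1 = k1, n1 = n1, k2 = k2, n2 = n2)
}

#' Cohen's d with pooled standard deviation
#'
#' Standardized mean difference (mean(a) - mean(b)) / s_pooled, with the
#' pooled SD using n - 1 denominators. The sign follows a - b; swapping the
#' arguments flips the sign and preserves the magnitude.
#'
#' @param a,b numeric samples, each with >= 2 values and finite variance.
#' @return numeric effect size.
#' @examples
#' cohensD(c(1, 2, 3), c(4, 5, 6))  # -3
#' @export
cohensD <- function(a, b) {
  stopIfNot1(length(a) >= 2 && length(b) >= 2,
             "each sample needs at least 2 values")
  va <- stats::var(a); vb <- stats::var(b)
  stopIfNot1(is.finite(va) && is.finite(vb), "samples must have finite variance")
  sp2 <- ((length(a) - 1) * va + (length(b) - 1) * vb) /
    (length(a) + length(b) - 2)
  stopIfNot1(sp2 > 0, "pooled standard deviation is zero")
  (mean(a) - mean(b)) / sqrt(sp2)
}
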