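#' Exact binomial test of equal count distributions
#'
#' Two-sided exact test of `k` successes in `n` trials under success
#' probability 1/2, using the minimum-likelihood rule: the p-value sums the
#' probabilities of all outcomes no more likely than the observed one
#' (capped at 1).  At p = 1/2 the distribution is symmetric, so this equals
#' the doubled tail.
#'
#' @param k observed successes (0..n).
#' @param n trials (>= 1).
#' @return `htest` with `statistic` (k), `parameter` (n) and `p.value`.
#' @examples
#' binomial_equal_test(3, 13)$p.value  # 756/8192
#' @export
binomial_equal_test <- function(k, n) {
  if (n < 1 || k < 0 || k > n) stop_invalid("need 0 <= k <= n, n >= 1")
  d <- stats::dbinom(0:n, n, 0.5)
  # relative tolerance guards against FP noise in "equally likely" outcomes
  p <- min(1, sum(d[d <= d[k + 1] * (1 + 1e-7)]))
  structure(list(statistic = c(k = k), parameter = c(n = n), p.value = p,
                 method = "exact binomial test (p = 1/2, minimum likelihood)",
                 data.name = sprintf("%d successes in %d trials", k, n)),
            class = "htest")
}
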