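#' Mann-Whitney U test (exact or tie-corrected normal approximation)
#'
#' The statistic reported is `min(U, n1*n2 - U)` where
#' `U = #\{(x_i, y_j): x_i < y_j\} + 0.5 #\{ties\}`.  With `method =
#' "auto"` the exact two-sided p (twice the lower tail of the exact U
#' distribution, capped at 1) is used when `n1 + n2 <= 16` and the pooled
#' data are tie-free; otherwise a tie-corrected normal approximation with
#' continuity correction is used.
#'
#' @param x,y non-empty numeric samples.
#' @param method `"auto"` (default), `"exact"` or `"normal"`.
#' @param correct continuity correction for the normal path (default
#'   TRUE).
#' @return an object of class `htest` with `statistic` (U), `p.value` and
#'   a `z` element on the normal path.
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))$p.value  # 1/3 exactly
#' @export
mann_whitney <- function(x, y, method = c("auto", "exact", "normal"),
                         correct = TRUE) {
  method <- match.arg(method)
  if (!length(x) || !length(y)) stop_invalid("samples must be non-empty")
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  ties <- any(duplicated(pooled))
  # U counting x_i < y_j (+ half-ties), via the rank-sum identity
  U_gt <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2   # pairs x > y (+ ties/2)
  U <- n1 * n2 - U_gt
  u_min <- min(U, n1 * n2 - U)
  if (method == "auto")
    method <- if (n1 + n2 <= 16 && !ties) "exact" else "normal"
  z <- NULL
  if (method == "exact") {
    if (ties) stop_invalid("exact method requires tie-free data")
    p <- min(1, 2 * stats::pwilcox(u_min, n1, n2))
  } else {
    N <- n1 + n2
    tt <- table(pooled)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(tt^3 - tt) / (N * (N - 1)))
    mu <- n1 * n2 / 2
    cc <- if (correct) sign(U - mu) * 0.5 else 0
    z <- if (sigma2 > 0) (U - mu - cc) / sqrt(sigma2) else 0
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  structure(list(statistic = c(U = u_min), p.value = p, z = z,
                 method = paste0("Mann-Whitney U test (", method, ")"),
                 alternative = "two.sided",
                 data.name = sprintf("x (n=%d), y (n=%d)", n1, n2)),
            class = "htest")
}

#' Kruskal-Wallis rank test with tie correction
#'
#' `H = [12 / (N(N+1)) * sum R_j^2 / n_j - 3(N+1)] / (1 - sum(t^3 - t) /
#' (N^3 - N))` on pooled midranks; p from the chi-square distribution with
#' k - 1 degrees of freedom.  All-identical data return H = 0, p = 1 by
#' convention.
#'
#' @param groups list of >= 2 non-empty numeric samples.
#' @return `htest` with `statistic` (H), `parameter` (df) and `p.value`.
#' @examples
#' kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))$statistic  # 4.5714
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2L) stop_invalid("need at least 2 groups")
  if (any(!vapply(groups, length, 1L)))
    stop_invalid("groups must be non-empty")
  pooled <- unlist(groups)
  N <- length(pooled)
  r <- rank(pooled)
  g <- rep(seq_along(groups), vapply(groups, length, 1L))
  Rj <- tapply(r, g, sum)
  nj <- tapply(r, g, length)
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / nj) - 3 * (N + 1)
  tt <- table(pooled)
  corr <- 1 - sum(tt^3 - tt) / (N^3 - N)
  H <- if (corr > 0) H / corr else 0
  df <- length(groups) - 1L
  structure(list(statistic = c(H = H), parameter = c(df = df),
                 p.value = if (H <= 0) 1 else
                   stats::pchisq(H, df, lower.tail = FALSE),
                 method = "Kruskal-Wallis rank test (tie-corrected)",
                 data.name = sprintf("%d groups, N = %d",
                                     length(groups), N)),
            class = "htest")
}

#' Steel-Dwass all-pairs nonparametric post-hoc comparisons
#'
#' For each pair of groups a standardized two-sample rank statistic is
#' computed on that pair's pooled midranks, and the adjusted p-value is
#' taken from the studentized-range distribution with `k` groups and
#' infinite degrees of freedom: `p = Pr(Q >= |z| * sqrt(2))`.  This is the
#' usual large-sample form; a warning is emitted when any group has fewer
#' than 8 observations.
#'
#' @param groups list of >= 3 numeric samples, each of size >= 2.
#' @return symmetric matrix of adjusted p-values (diagonal NA).
#' @export
steel_dwass <- function(groups) {
  k <- length(groups)
  if (k < 3L) stop_invalid("need at least 3 groups")
  if (any(vapply(groups, length, 1L) < 2L))
    stop_invalid("every group needs at least 2 observations")
  if (any(vapply(groups, length, 1L) < 8L))
    warning("group with n < 8: studentized-range approximation is rough")
  nm <- names(groups) %||% paste0("g", seq_len(k))
  P <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    xi <- groups[[i]]; xj <- groups[[j]]
    ni <- length(xi); nj <- length(xj); N <- ni + nj
    r <- rank(c(xi, xj))
    W <- sum(r[seq_len(ni)])
    E <- ni * (N + 1) / 2
    tt <- table(c(xi, xj))
    V <- ni * nj / 12 * ((N + 1) - sum(tt^3 - tt) / (N * (N - 1)))
    z <- if (V > 0) (W - E) / sqrt(V) else 0
    P[i, j] <- P[j, i] <-
      stats::ptukey(abs(z) * sqrt(2), nmeans = k, df = Inf,
                    lower.tail = FALSE)
  }
  P
}
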