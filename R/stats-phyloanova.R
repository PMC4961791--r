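#' Simulation-based phylogenetic analysis of variance
#'
#' Computes the classical one-way ANOVA F statistic for a tip trait and
#' calibrates it against a null distribution obtained by simulating
#' Brownian motion on the phylogeny (Garland-style): the BM rate is
#' estimated from the data by the GLS closed form with the phylogenetic
#' mean, `sigma2 = (x - a)' C^{-1} (x - a) / (n - 1)` with
#' `a = (1'C^{-1}x) / (1'C^{-1}1)`, traits are re-simulated `n_sim` times
#' and F recomputed with the same group labels.  The p-value is
#' `(1 + #\{F_sim >= F_obs\}) / (n_sim + 1)`.
#'
#' @param tree a `ape::phylo` whose tips match the trait names.
#' @param traits a `trait_vector` from [simulate_bm_traits()], or a named
#'   numeric vector (then `groups` is required).
#' @param groups named vector tip -> group (ignored when `traits` is a
#'   `trait_vector`); >= 2 groups, each with >= 2 tips.
#' @param n_sim number of Brownian simulations (default 1000).
#' @param seed integer seed.
#' @return `htest` with `statistic` (F), `parameter` (df), `p.value` and
#'   `sigma2`.
#' @export
phylo_anova <- function(tree, traits, groups = NULL, n_sim = 1000,
                        seed = 1L) {
  if (inherits(traits, "trait_vector")) {
    groups <- traits$group
    traits <- traits$value
  }
  tips <- tree$tip.label
  if (!all(tips %in% names(traits)) || !all(tips %in% names(groups)))
    stop_invalid("traits and groups must cover every tip")
  x <- as.numeric(traits[tips])
  g <- factor(as.character(groups[tips]))
  if (nlevels(g) < 2L) stop_invalid("need at least 2 groups")
  if (any(table(g) < 2L))
    stop_invalid("every group needs at least 2 tips")
  if (stats::var(x) == 0)
    stop_invalid("trait has zero variance: F is undefined")
  n <- length(x); k <- nlevels(g)
  f_obs <- anova_f(x, g)
  C <- ape::vcv(tree)[tips, tips]
  Ci <- solve(C)
  one <- rep(1, n)
  a <- drop(one %*% Ci %*% x) / drop(one %*% Ci %*% one)
  sig2 <- drop((x - a) %*% Ci %*% (x - a)) / (n - 1)
  R <- chol(C)
  f_sim <- withr::with_seed(stream_seed(seed, "phyloanova"), {
    Z <- matrix(rnorm(n * n_sim), n, n_sim)
    X <- crossprod(R, Z) * sqrt(sig2)
    anova_f_cols(X, g)
  })
  p <- (1 + sum(f_sim >= f_obs)) / (n_sim + 1)
  structure(list(statistic = c(F = f_obs),
                 parameter = c(df1 = k - 1L, df2 = n - k),
                 p.value = p, sigma2 = sig2, n_sim = n_sim,
                 method = "phylogenetic ANOVA (Brownian-motion null)",
                 data.name = sprintf("%d tips, %d groups", n, k)),
            class = "htest")
}

anova_f <- function(x, g) {
  n <- length(x); k <- nlevels(g)
  gm <- tapply(x, g, mean)
  ng <- tabulate(g)
  ssb <- sum(ng * (gm - mean(x))^2)
  ssw <- sum((x - gm[g])^2)
  (ssb / (k - 1)) / (ssw / (n - k))
}

# column-wise F over a matrix of simulated traits (same groups)
anova_f_cols <- function(X, g) {
  n <- nrow(X); k <- nlevels(g)
  ng <- tabulate(g)
  gm <- rowsum(X, g) / ng                       # k x nsim group means
  cm <- colMeans(X)
  ssb <- colSums(ng * (gm - rep(cm, each = k))^2)
  tot <- colSums(X^2) - n * cm^2
  ssw <- tot - ssb
  (ssb / (k - 1)) / (ssw / (n - k))
}
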