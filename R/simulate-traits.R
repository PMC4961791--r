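#' Simulate Brownian-motion traits on a tree with optional group offsets
#'
#' Draws one multivariate-normal realization of Brownian motion with rate
#' `sigma2` on the tree (covariance `sigma2 * C`, where `C[i, j]` is the
#' shared root-to-MRCA path length of tips i and j) and adds a fixed offset
#' per group.  This is the generative counterpart of the Brownian null used
#' by [phylo_anova()].
#'
#' @param tree a dated `ape::phylo`.
#' @param sigma2 Brownian rate (> 0, trait variance per MY).
#' @param groups named character/factor: tip label -> group.
#' @param group_effects named numeric: group -> additive offset (groups
#'   missing from this vector get offset 0).
#' @param seed integer seed.
#' @return a `trait_vector`: list with `value` (named numeric per tip) and
#'   `group` (named character per tip).
#' @export
simulate_bm_traits <- function(tree, sigma2, groups,
                               group_effects = NULL, seed = 1L) {
  stopifnot(inherits(tree, "phylo"), sigma2 > 0)
  tips <- tree$tip.label
  if (!all(tips %in% names(groups)))
    stop_invalid("every tip needs a group label")
  groups <- as.character(groups[tips])
  names(groups) <- tips
  C <- ape::vcv(tree)[tips, tips]
  R <- chol(C)
  x <- withr::with_seed(stream_seed(seed, "bm"), {
    drop(crossprod(R, rnorm(length(tips)))) * sqrt(sigma2)
  })
  off <- if (is.null(group_effects)) rep(0, length(tips)) else {
    o <- group_effects[groups]
    o[is.na(o)] <- 0
    o
  }
  structure(list(value = setNames(x + off, tips), group = groups),
            class = "trait_vector")
}
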