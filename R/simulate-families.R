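#' Simulate gene-family size evolution along a dated tree
#'
#' Each family starts at a root size of `1 + Poisson(root_mean - 1)` and
#' evolves down every branch by a stepwise birth-death process: the number
#' of size-change events on a branch is Poisson with mean
#' `base_lambda * branch_MY`, and each event adds or removes one gene copy
#' with equal probability (a removal at size 0 is a no-op, so counts stay
#' non-negative).  An optional `shift` multiplies the event intensity on
#' every branch inside the clade rooted at a chosen internal node, modelling
#' accelerated family turnover in that clade.
#'
#' @param tree a dated `ape::phylo`.
#' @param n_families number of families (rows).
#' @param base_lambda size-change events per MY per family.
#' @param shift optional `list(node =, multiplier =)`; `node` is an ape
#'   internal node number whose subtending branch and descendants get
#'   `base_lambda * multiplier`.
#' @param root_mean mean root family size (default 5).
#' @param seed integer seed.
#' @return integer matrix, families x species (columns named by tip label).
#' @export
simulate_family_counts <- function(tree, n_families, base_lambda,
                                   shift = NULL, root_mean = 5, seed = 1L) {
  stopifnot(inherits(tree, "phylo"), n_families >= 1, base_lambda >= 0)
  ntip <- length(tree$tip.label)
  if (!is.null(shift)) {
    if (shift$node <= ntip || shift$node > ntip + tree$Nnode)
      stop_invalid("shift node must be an internal node")
  }
  shifted <- if (is.null(shift)) integer() else
    c(shift$node, phangorn_free_desc(tree, shift$node))
  ctree <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  withr::with_seed(stream_seed(seed, "families"), {
    counts <- matrix(0L, nrow = n_families, ncol = ntip + tree$Nnode)
    counts[, ntip + 1L] <- 1L + stats::rpois(n_families,
                                             max(root_mean - 1, 0))
    edges <- ctree$edge
    lens <- ctree$edge.length
    for (k in seq_len(nrow(edges))) {
      par <- edges[k, 1L]; chi <- edges[k, 2L]
      lam <- base_lambda *
        (if (!is.null(shift) && chi %in% shifted) shift$multiplier else 1)
      n_ev <- stats::rpois(n_families, lam * lens[k])
      state <- counts[, par]
      mx <- if (length(n_ev)) max(n_ev) else 0L
      for (s in seq_len(mx)) {
        act <- n_ev >= s
        step <- sample(c(-1L, 1L), sum(act), replace = TRUE)
        state[act] <- pmax(0L, state[act] + step)
      }
      counts[, chi] <- state
    }
    out <- counts[, seq_len(ntip), drop = FALSE]
    colnames(out) <- tree$tip.label
    rownames(out) <- sprintf("fam%04d", seq_len(n_families))
    out
  })
}

# nodes (tips and internals) descending from `node`, excluding `node`
phangorn_free_desc <- function(tree, node) {
  kids <- tree$edge[tree$edge[, 1L] == node, 2L]
  if (!length(kids)) return(integer())
  c(kids, unlist(lapply(kids, phangorn_free_desc, tree = tree)))
}
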