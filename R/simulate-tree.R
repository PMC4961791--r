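#' Simulate a dated, rooted, ultrametric phylogeny
#'
#' Draws a random coalescent topology and rescales node depths so that the
#' crown (root) age equals `crown_age` exactly, with all tips at age 0.
#' Identical arguments always yield an identical tree.
#'
#' @param n_taxa number of tips (>= 2).
#' @param crown_age root age in millions of years (> 0).
#' @param seed integer seed; the function leaves the global RNG state
#'   untouched.
#' @return a rooted binary ultrametric `ape::phylo` with tip labels
#'   `t1..tn` and branch lengths in MY.
#' @examples
#' tr <- simulate_tree(8, 60, seed = 42)
#' max(node_ages(tr))  # 60
#' @export
simulate_tree <- function(n_taxa, crown_age, seed = 1L) {
  if (!is.numeric(n_taxa) || n_taxa < 2)
    stop_invalid("n_taxa must be >= 2")
  if (!is.numeric(crown_age) || crown_age <= 0)
    stop_invalid("crown_age must be > 0")
  n_taxa <- as.integer(n_taxa)
  tree <- withr::with_seed(stream_seed(seed, "topology"), {
    ape::rcoal(n_taxa, tip.label = paste0("t", seq_len(n_taxa)))
  })
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length * (crown_age / depth)
  tree
}
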