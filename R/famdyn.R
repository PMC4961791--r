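#' Consistently expanded / contracted families at an ancestral node
#'
#' A family counts as expanded at an internal node iff its smallest size
#' among the node's descendant (in-clade) species strictly exceeds its
#' largest size among all other (out-clade) species, and as contracted iff
#' its largest in-clade size is strictly below its smallest out-clade size.
#' Strict inequalities mean ties are never counted, and a family can never
#' be both.
#'
#' @param counts non-negative integer matrix, families x species; column
#'   names must match the tree's tip labels.
#' @param tree a rooted `ape::phylo`.
#' @param node internal node (ape node number, > number of tips); the root
#'   is rejected because it has no out-clade.
#' @return named integer vector `c(n_expanded, n_contracted)`.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' m <- matrix(c(5, 6, 2, 1), 1, dimnames = list("f1", c("A", "B", "C", "D")))
#' consistent_dynamics(m, tr, ape::getMRCA(tr, c("A", "B")))
#' @export
consistent_dynamics <- function(counts, tree, node) {
  cols <- check_counts(counts, tree)
  ntip <- length(tree$tip.label)
  if (node <= ntip || node > ntip + tree$Nnode)
    stop_invalid("node must be an internal node number")
  if (node == ntip + 1L)
    stop_invalid("the root has no out-clade; dynamics are undefined there")
  inc <- cols[clade_tips(tree, node)]
  outc <- setdiff(cols, inc)
  node_counts(counts, inc, outc)
}

# vectorized min/max comparison for one node
node_counts <- function(m, inc, outc) {
  in_min <- row_min(m, inc); in_max <- row_max(m, inc)
  out_min <- row_min(m, outc); out_max <- row_max(m, outc)
  c(n_expanded = sum(in_min > out_max),
    n_contracted = sum(in_max < out_min))
}

check_counts <- function(counts, tree) {
  if (is.null(colnames(counts)) ||
      !setequal(colnames(counts), tree$tip.label))
    stop_invalid("counts columns must match tree tip labels")
  if (any(counts < 0)) stop_invalid("family counts must be non-negative")
  match(tree$tip.label, colnames(counts))
}

#' Permutation envelopes for node-wise expansion / contraction counts
#'
#' Each permutation independently shuffles every family's counts across
#' species (preserving each family's size spectrum while breaking the
#' phylogenetic association), recomputes the expanded / contracted counts
#' at each requested internal node, and reports the empirical 5th and 95th
#' percentiles (type-7 linear interpolation) together with the observed
#' values.  `mode = "columns"` instead permutes whole species columns,
#' preserving within-species size profiles.
#'
#' @inheritParams consistent_dynamics
#' @param n_perm number of permutations (>= 100; default 1000).
#' @param seed integer seed; output is deterministic given the seed.
#' @param nodes internal node numbers to evaluate (default: every internal
#'   node except the root).
#' @param mode permutation unit: `"within_family"` (default) or
#'   `"columns"`.
#' @return a `node_dynamics` data.frame: one row per node with observed
#'   `n_expanded` / `n_contracted` and their permutation percentiles
#'   (`exp_p05`, `exp_p95`, `con_p05`, `con_p95`), plus `n_perm` and
#'   `seed`.
#' @export
permutation_percentiles <- function(counts, tree, n_perm = 1000, seed = 1L,
                                    nodes = NULL,
                                    mode = c("within_family", "columns")) {
  mode <- match.arg(mode)
  if (n_perm < 100) stop_invalid("n_perm must be >= 100")
  cols <- check_counts(counts, tree)
  ntip <- length(tree$tip.label)
  if (is.null(nodes))
    nodes <- setdiff((ntip + 1L):(ntip + tree$Nnode), ntip + 1L)
  if (any(nodes <= ntip) || any(nodes > ntip + tree$Nnode) ||
      (ntip + 1L) %in% nodes)
    stop_invalid("nodes must be internal, non-root node numbers")
  m <- as.matrix(counts)
  nfam <- nrow(m); k <- ncol(m)
  in_cols <- lapply(nodes, function(nd) cols[clade_tips(tree, nd)])
  out_cols <- lapply(in_cols, function(ic) setdiff(seq_len(k), ic))
  obs <- mapply(function(ic, oc) node_counts(m, ic, oc),
                in_cols, out_cols)
  perm_exp <- matrix(0L, n_perm, length(nodes))
  perm_con <- matrix(0L, n_perm, length(nodes))
  row_of <- rep.int(seq_len(nfam), k)
  withr::with_seed(stream_seed(seed, "famperm"), {
    for (p in seq_len(n_perm)) {
      pm <- if (mode == "within_family") {
        # vectorized within-row shuffle: order by (row, random key)
        o <- order(row_of, runif(nfam * k))
        matrix(m[o], nrow = nfam, byrow = TRUE)
      } else m[, sample.int(k), drop = FALSE]
      for (j in seq_along(nodes)) {
        nc <- node_counts(pm, in_cols[[j]], out_cols[[j]])
        perm_exp[p, j] <- nc[1L]; perm_con[p, j] <- nc[2L]
      }
    }
  })
  q <- function(x) stats::quantile(x, c(0.05, 0.95), type = 7, names = FALSE)
  qe <- apply(perm_exp, 2L, q); qc <- apply(perm_con, 2L, q)
  out <- data.frame(node = nodes,
                    n_expanded = obs[1L, ], n_contracted = obs[2L, ],
                    exp_p05 = qe[1L, ], exp_p95 = qe[2L, ],
                    con_p05 = qc[1L, ], con_p95 = qc[2L, ],
                    n_perm = n_perm, seed = seed)
  class(out) <- c("node_dynamics", "data.frame")
  attr(out, "mode") <- mode
  out
}
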