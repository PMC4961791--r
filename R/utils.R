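# Internal helpers shared across modules.

# Deterministic stream seed derived from a master seed and a string key.
# Polynomial rolling hash reduced mod a Mersenne-ish prime < 2^31 so the
# result is always a valid `set.seed()` value.  Used to give every simulated
# branch / table its own reproducible RNG stream.
stream_seed <- function(master, key) {
  stopifnot(length(master) == 1L, is.finite(master))
  bytes <- utf8ToInt(paste0(format(master, scientific = FALSE), "|", key))
  h <- 17
  for (b in bytes) h <- (h * 131 + b) %% 2147483629
  as.integer(h)
}

# Cheap FNV-style string hash used to fingerprint configurations in output
# metadata (not cryptographic).
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 2166136261 %% 2147483629
  for (b in bytes) h <- ((h * 16777619) %% 2147483629 + b) %% 2147483629
  sprintf("%08x", h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) stop(..., call. = FALSE)

# Validate a gene annotation table (gene_id, scaffold, start, end, strand).
check_annotation <- function(g) {
  need <- c("gene_id", "scaffold", "start", "end", "strand")
  if (!is.data.frame(g) || !all(need %in% names(g)))
    stop_invalid("annotation must be a data.frame with columns ",
                 paste(need, collapse = ", "))
  if (anyDuplicated(g$gene_id))
    stop_invalid("duplicate gene ids in annotation")
  if (any(g$start > g$end)) stop_invalid("gene start > end")
  if (!all(g$strand %in% c("+", "-")))
    stop_invalid("strand must be '+' or '-'")
  invisible(g)
}

# Age (time before present, MY) of every node of a rooted dated tree.
#' Node ages of a dated tree
#'
#' Ages are measured in the units of the branch lengths (millions of years
#' throughout this package), with the deepest tip at age 0.
#'
#' @param tree a rooted `ape::phylo` with branch lengths.
#' @return numeric vector of ages indexed by ape node number
#'   (tips `1..n`, then internal nodes).
#' @export
node_ages <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  max(depth) - depth
}

#' Age of the most recent common ancestor of two tips
#'
#' @param tree a rooted dated `ape::phylo`.
#' @param a,b tip labels.
#' @return age of the MRCA in MY.
#' @export
mrca_age <- function(tree, a, b) {
  if (!all(c(a, b) %in% tree$tip.label))
    stop_invalid("tips not in tree: ", paste(setdiff(c(a, b), tree$tip.label),
                                             collapse = ", "))
  node_ages(tree)[ape::getMRCA(tree, c(a, b))]
}

# Tip indices (column positions in tip.label order) descending from a node.
clade_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, clade_tips, tree = tree))
}

# Row-wise parallel min / max over selected columns of a matrix.
row_min <- function(m, cols) do.call(pmin, lapply(cols, function(j) m[, j]))
row_max <- function(m, cols) do.call(pmax, lapply(cols, function(j) m[, j]))
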