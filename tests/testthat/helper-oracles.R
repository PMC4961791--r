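# Independent reference implementations (oracles) used only by the tests.

# Build a minimal annotation from a vector of gene ids in order, optionally
# split over scaffolds (named list scaffold -> ids) and with strands.
make_annotation <- function(ids, scaffold = "S1", strand = NULL) {
  if (is.list(ids)) {
    rows <- lapply(names(ids), function(s)
      make_annotation(ids[[s]], scaffold = s))
    g <- do.call(rbind, rows)
    rownames(g) <- NULL
    return(g)
  }
  n <- length(ids)
  start <- (seq_len(n) - 1L) * 1100L + 1L
  data.frame(gene_id = ids, scaffold = scaffold, start = start,
             end = start + 999L,
             strand = strand %||% rep("+", n),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pair_df <- function(a, b, species = NULL) {
  p <- data.frame(gene_a = a, gene_b = b, stringsAsFactors = FALSE)
  if (!is.null(species)) attr(p, "species") <- species
  p
}

# --- synteny oracle ------------------------------------------------------
# Enumerates maximal legal chains from first principles: joinability of two
# anchors is decided by explicitly listing the annotated genes lying
# between them in each genome; chains are walked anchor by anchor;
# inversions are counted by scanning for starts of strictly-descending
# runs.  Returns the canonical anchor partition of valid blocks.
oracle_blocks <- function(ga, gb, pairs, min_genes = 5, max_gap = 4,
                          max_inversions = 5) {
  ga <- order_genes(ga); gb <- order_genes(gb)
  loc <- function(g, id) g[match(id, g$gene_id), c("scaffold", "idx")]
  la <- loc(ga, pairs$gene_a); lb <- loc(gb, pairs$gene_b)
  anch <- data.frame(id = pairs$gene_a, sa = la$scaffold, ia = la$idx,
                     sb = lb$scaffold, ib = lb$idx,
                     stringsAsFactors = FALSE)
  between <- function(g, scaf, i1, i2) {
    lohi <- range(c(i1, i2))
    sum(g$scaffold == scaf & g$idx > lohi[1] & g$idx < lohi[2])
  }
  joinable <- function(a1, a2) {
    a1$sa == a2$sa && a1$sb == a2$sb &&
      between(ga, a1$sa, a1$ia, a2$ia) <= max_gap &&
      between(gb, a1$sb, a1$ib, a2$ib) <= max_gap
  }
  blocks <- list()
  for (key in unique(paste(anch$sa, anch$sb))) {
    sub <- anch[paste(anch$sa, anch$sb) == key, , drop = FALSE]
    sub <- sub[order(sub$ia), , drop = FALSE]
    i <- 1L
    while (i <= nrow(sub)) {
      j <- i
      while (j < nrow(sub) && joinable(sub[j, ], sub[j + 1L, ])) j <- j + 1L
      chain <- sub[i:j, , drop = FALSE]
      # count starts of strictly descending runs in ib
      inv <- 0L
      if (nrow(chain) > 1L)
        for (r in 2:nrow(chain))
          if (chain$ib[r] < chain$ib[r - 1L] &&
              (r == 2L || chain$ib[r - 1L] >= chain$ib[r - 2L]))
            inv <- inv + 1L
      if (nrow(chain) >= min_genes && inv <= max_inversions)
        blocks[[length(blocks) + 1L]] <- sort(chain$id)
      i <- j + 1L
    }
  }
  canonical_partition(blocks)
}

canonical_partition <- function(blocks) {
  out <- lapply(blocks, sort)
  out[order(vapply(out, `[`, "", 1L))]
}

blocks_partition <- function(blocks) {
  canonical_partition(lapply(blocks, function(b) b$gene_a))
}

# random small synteny instance: two genomes sharing some orthologues with
# scrambled order/scaffolds in B
random_instance <- function(max_genes = 30, max_anchors = 15) {
  na <- sample(5:max_genes, 1)
  nb <- sample(5:max_genes, 1)
  ids_a <- sprintf("a%02d", seq_len(na))
  ids_b <- sprintf("b%02d", seq_len(nb))
  nsc_a <- sample(1:2, 1); nsc_b <- sample(1:2, 1)
  ga <- make_annotation(split(ids_a, sort(rep_len(seq_len(nsc_a), na))))
  gb <- make_annotation(split(sample(ids_b),
                              sort(rep_len(seq_len(nsc_b), nb))))
  k <- sample(2:min(max_anchors, na, nb), 1)
  # gb order is a random permutation, so anchors are well scrambled
  list(ga = ga, gb = gb,
       pairs = pair_df(sample(ids_a, k), sample(ids_b, k)))
}

# --- Mann-Whitney enumeration oracle -------------------------------------
mwu_enum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_of <- function(xi, yi) sum(outer(xi, yi, "<"))
  u_obs <- u_of(x, y)
  u_min <- min(u_obs, n1 * n2 - u_obs)
  idx <- combn(n1 + n2, n1)
  us <- apply(idx, 2, function(ii) u_of(pooled[ii], pooled[-ii]))
  min(1, 2 * mean(us <= u_min))
}

# --- unconstrained OLS branch-length oracle via pseudoinverse ------------
ols_fit_oracle <- function(tree, D) {
  tips <- tree$tip.label
  n <- length(tips)
  pairs <- t(combn(n, 2))
  paths <- lapply(seq_len(nrow(pairs)), function(r)
    ape::nodepath(tree, pairs[r, 1], pairs[r, 2]))
  edges <- tree$edge
  A <- matrix(0, nrow(pairs), nrow(edges))
  for (r in seq_len(nrow(pairs))) {
    nd <- paths[[r]]
    for (s in seq_len(length(nd) - 1)) {
      e <- which((edges[, 1] == nd[s] & edges[, 2] == nd[s + 1]) |
                   (edges[, 2] == nd[s] & edges[, 1] == nd[s + 1]))
      A[r, e] <- 1
    }
  }
  d <- D[tips, tips][pairs]
  drop(MASS::ginv(A) %*% d)
}

# Random dated tree plus additive distances from known branch lengths.
# Only the sum of the two root-adjacent branch lengths is identifiable
# from leaf-pair distances, and the fitter reports that sum split in
# proportion to branch durations; the generating lengths honour the same
# convention so that full recovery is well defined.
random_additive_case <- function(n_leaves, seed) {
  tr <- simulate_tree(n_leaves, crown_age = 50, seed = seed)
  true_len <- withr::with_seed(seed + 1000, runif(nrow(tr$edge), 0.01, 0.5))
  root_edges <- which(tr$edge[, 1] == n_leaves + 1)
  dur <- tr$edge.length[root_edges]
  true_len[root_edges] <- sum(true_len[root_edges]) * dur / sum(dur)
  loss_tr <- tr
  loss_tr$edge.length <- true_len
  D <- ape::cophenetic.phylo(loss_tr)
  list(tree = tr, true_len = true_len, D = D)
}
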