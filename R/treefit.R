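#' Fit synteny-loss branch lengths on a fixed dated topology
#'
#' Weighted least-squares (Fitch-Margoliash) fitting of a distance matrix
#' onto a user-supplied topology: minimizes
#' `sum_{i<j} w_ij (d_ij - path_ij(b))^2` over branch lengths `b`, with
#' `w_ij = d_ij^(-P)` (`w_ij = 1` where `d_ij = 0`).  The system is solved
#' as weighted linear least squares on the leaf-pair x branch
#' path-incidence matrix; with `nonneg = TRUE` (default) the non-negative
#' solution is found by Lawson-Hanson active-set iteration (not by
#' truncating an unconstrained fit).  For a rooted binary topology the two
#' root-adjacent branches appear in every path together and are estimable
#' only as a sum; their fitted total is split in proportion to their time
#' durations and flagged.
#'
#' @param topology a rooted `ape::phylo` with branch lengths in MY (the
#'   dated tree; durations are carried into the fit for rate conversion).
#' @param D symmetric distance matrix (or `dist`) with dimnames matching
#'   the tip labels; >= 3 leaves.
#' @param weight_power P in `w = d^-P`; 0 (OLS), 1 or 2 (default 2, the
#'   Fitch-Margoliash weighting).
#' @param nonneg constrain branch lengths to be >= 0 (default TRUE).
#' @return a `branch_fit`: list with `edge` (data.frame: parent, child,
#'   duration, loss, root_pair flag), `rss` (weighted residual sum of
#'   squares), `weight_power`, `nonneg`, and the `tree`.
#' @examples
#' tr <- ape::read.tree(text = "(A:1,B:1,C:1);")
#' D <- matrix(c(0, .3, .4, .3, 0, .5, .4, .5, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' fit_branch_lengths(tr, D)$edge$loss  # 0.1 0.2 0.3
#' @export
fit_branch_lengths <- function(topology, D, weight_power = 2,
                               nonneg = TRUE) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  tips <- topology$tip.label
  if (is.null(rownames(D)) || !setequal(rownames(D), tips))
    stop_invalid("leaf sets of topology and distance matrix differ")
  if (length(tips) < 3L)
    stop_invalid("need at least 3 leaves to fit branch lengths")
  if (max(abs(D - t(D))) > 1e-8) stop_invalid("distance matrix not symmetric")
  D <- D[tips, tips]
  n <- length(tips)
  edges <- topology$edge
  nedge <- nrow(edges)
  # incidence: rows = leaf pairs, cols = edges on the i-j path
  pairs <- t(combn(n, 2L))
  A <- matrix(0, nrow(pairs), nedge)
  anc <- edge_chain_to_root(topology)
  for (r in seq_len(nrow(pairs))) {
    e1 <- anc[[pairs[r, 1L]]]; e2 <- anc[[pairs[r, 2L]]]
    A[r, c(setdiff(e1, e2), setdiff(e2, e1))] <- 1
  }
  d <- D[pairs]
  w <- ifelse(d > 0, d^(-weight_power), 1)
  # root-adjacent columns are identical for a binary root: merge them
  root <- n + 1L
  root_children <- which(edges[, 1L] == root)
  merged <- NULL
  cols <- seq_len(nedge)
  if (length(root_children) == 2L) {
    merged <- root_children
    A <- cbind(A[, -merged, drop = FALSE], A[, merged[1L]])
    cols <- c(setdiff(seq_len(nedge), merged), NA)
  }
  sw <- sqrt(w)
  Aw <- A * sw
  dw <- d * sw
  b <- if (nonneg) pracma::lsqnonneg(Aw, dw)$x else
    qr.coef(qr(Aw), dw)
  b[is.na(b)] <- 0
  fitted_len <- numeric(nedge)
  if (is.null(merged)) {
    fitted_len[cols] <- b
  } else {
    fitted_len[cols[-length(cols)]] <- b[-length(b)]
    dur <- topology$edge.length[merged]
    prop <- if (sum(dur) > 0) dur / sum(dur) else c(0.5, 0.5)
    fitted_len[merged] <- b[length(b)] * prop
  }
  rss <- sum(w * (drop(A %*% b) - d)^2)
  ed <- data.frame(parent = edges[, 1L], child = edges[, 2L],
                   duration = topology$edge.length,
                   loss = fitted_len,
                   root_pair = seq_len(nedge) %in% merged)
  structure(list(edge = ed, rss = rss, weight_power = weight_power,
                 nonneg = nonneg, tree = topology),
            class = "branch_fit")
}

# for each tip, the edge indices on its path to the root
edge_chain_to_root <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  parent_edge <- integer(ntip + tree$Nnode)
  parent_edge[tree$edge[, 2L]] <- seq_len(nrow(tree$edge))
  lapply(seq_len(ntip), function(tip) {
    path <- integer()
    nd <- tip
    while (nd != root) {
      e <- parent_edge[nd]
      path <- c(path, e)
      nd <- tree$edge[e, 1L]
    }
    path
  })
}

#' @export
print.branch_fit <- function(x, ...) {
  cat(sprintf("branch_fit: %d branches, weighted RSS = %.3g (P = %g%s)\n",
              nrow(x$edge), x$rss, x$weight_power,
              if (x$nonneg) ", nonneg" else ""))
  invisible(x)
}

#' Per-branch loss rates from a branch fit
#'
#' Converts fitted per-branch loss lengths into per-MY rates by dividing by
#' the branch's time duration from the dated tree.  Branches of zero
#' duration get `NA` with a warning.
#'
#' @param fit a [fit_branch_lengths()] result.
#' @return the fit's `edge` table with an added `rate` column (loss / MY).
#' @export
branch_rates <- function(fit) {
  ed <- fit$edge
  zero <- ed$duration <= 0
  if (any(zero))
    warning(sum(zero), " zero-duration branch(es): rate reported as NA")
  ed$rate <- ifelse(zero, NA_real_, ed$loss / ed$duration)
  ed
}

#' Dated tree with fitted loss amounts as branch lengths
#'
#' @param fit a [fit_branch_lengths()] result.
#' @param what `"loss"` (default) or `"rate"` branch values.
#' @return an `ape::phylo` whose edge lengths are the fitted quantities,
#'   suitable for writing as annotated newick.
#' @export
as_loss_tree <- function(fit, what = c("loss", "rate")) {
  what <- match.arg(what)
  tr <- fit$tree
  tr$edge.length <- if (what == "loss") fit$edge$loss else
    branch_rates(fit)$rate
  tr
}
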