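#' Assign per-scaffold order indices to a gene annotation
#'
#' Genes are sorted by start coordinate within each scaffold (ties broken by
#' gene id) and given 0-based order indices; only these indices, not base
#' pairs, enter the synteny rules.
#'
#' @param g annotation data.frame (gene_id, scaffold, start, end, strand).
#' @return the annotation with an added integer column `idx`, sorted by
#'   scaffold and index.
#' @export
order_genes <- function(g) {
  check_annotation(g)
  o <- order(g$scaffold, g$start, g$gene_id)
  g <- g[o, , drop = FALSE]
  g$idx <- stats::ave(seq_len(nrow(g)), g$scaffold,
                      FUN = seq_along) - 1L
  rownames(g) <- NULL
  g
}

# anchors: one row per orthologue pair with positions in both genomes
compute_anchors <- function(ga, gb, pairs) {
  ga <- if (is.null(ga$idx)) order_genes(ga) else ga
  gb <- if (is.null(gb$idx)) order_genes(gb) else gb
  ia <- match(pairs$gene_a, ga$gene_id)
  ib <- match(pairs$gene_b, gb$gene_id)
  if (anyNA(ia) || anyNA(ib))
    stop_invalid("ortholog pair refers to a gene absent from an annotation")
  data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b,
             scaf_a = ga$scaffold[ia], idx_a = ga$idx[ia],
             scaf_b = gb$scaffold[ib], idx_b = gb$idx[ib],
             orientation = ifelse(ga$strand[ia] == gb$strand[ib],
                                  "same", "opposite"),
             stringsAsFactors = FALSE)
}

# number of maximal strictly-descending runs (length >= 2) in a sequence;
# the operational definition of "gene inversions" inside a block
descending_runs <- function(v) {
  if (length(v) < 2L) return(0L)
  d <- diff(v) < 0
  sum(d & !c(FALSE, d[-length(d)]))
}

#' Detect pairwise syntenic blocks
#'
#' Anchors (one-to-one orthologue pairs placed in both genomes) are grouped
#' by scaffold pair and sorted by position in genome A.  Chains grow greedily
#' left to right: the next anchor joins the current chain iff at most
#' `max_gap` annotated genes intervene between it and the previous anchor in
#' genome A *and* in genome B (the gap rule is enforced symmetrically in
#' both genomes).  A chain closes when the next anchor cannot join.  Chains
#' with at least `min_genes` anchors and at most `max_inversions` inversions
#' — counted as maximal strictly-descending runs of the genome-B indices —
#' are reported as blocks.  Every anchor belongs to at most one block.
#'
#' The defaults (5 contiguous genes, gaps of at most 4 genes, at most 5
#' inversions per block) are the classic rule set for gene-order synteny
#' between insect genomes.
#'
#' @param ga,gb annotations for the two species (indexed or not).
#' @param pairs an [rbh_pairs()] result (or any data.frame with `gene_a`,
#'   `gene_b`).
#' @param min_genes minimum anchors per block (default 5).
#' @param max_gap maximum intervening genes between consecutive anchors
#'   (default 4).
#' @param max_inversions maximum inversions per block (default 5).
#' @return a `synteny_blocks` object: list of anchor data.frames (each with
#'   attributes `n_anchors`, `inversions`), with attributes
#'   `n_anchors_total` (all anchors) and `params`.
#' @export
detect_blocks <- function(ga, gb, pairs, min_genes = 5, max_gap = 4,
                          max_inversions = 5) {
  anchors <- compute_anchors(ga, gb, pairs)
  blocks <- list()
  if (nrow(anchors)) {
    grp <- paste(anchors$scaf_a, anchors$scaf_b, sep = "\r")
    for (g in split(anchors, grp)) {
      g <- g[order(g$idx_a), , drop = FALSE]
      n <- nrow(g)
      join <- if (n > 1L)
        (g$idx_a[-1L] - g$idx_a[-n] - 1L) <= max_gap &
        (abs(g$idx_b[-1L] - g$idx_b[-n]) - 1L) <= max_gap
      else logical(0)
      chain <- cumsum(c(TRUE, !join))
      for (ch in split(g, chain)) {
        if (nrow(ch) < min_genes) next
        inv <- descending_runs(ch$idx_b)
        if (inv > max_inversions) next
        attr(ch, "n_anchors") <- nrow(ch)
        attr(ch, "inversions") <- inv
        blocks[[length(blocks) + 1L]] <- ch
      }
    }
  }
  structure(blocks, class = "synteny_blocks",
            n_anchors_total = nrow(anchors),
            params = list(min_genes = min_genes, max_gap = max_gap,
                          max_inversions = max_inversions))
}

#' @export
print.synteny_blocks <- function(x, ...) {
  cat("synteny_blocks:", length(x), "block(s),",
      sum(vapply(x, nrow, 1L)), "of", attr(x, "n_anchors_total"),
      "anchors in blocks\n")
  invisible(x)
}

#' Proportion of orthologue anchors inside syntenic blocks
#'
#' `p_s` is the fraction of one-to-one orthologue anchors assigned to valid
#' blocks; it equals 1 for identical gene orders and decreases as
#' rearrangements break blocks apart.
#'
#' @param blocks a [detect_blocks()] result.
#' @param pairs the pair set the blocks were computed from.
#' @return `p_s` in [0, 1].
#' @export
synteny_proportion <- function(blocks, pairs) {
  n_total <- nrow(pairs)
  if (is.null(n_total) || n_total == 0L)
    stop_invalid("no orthologue anchors: proportion synteny is undefined")
  sum(vapply(blocks, nrow, 1L)) / n_total
}

#' Exponential-decay synteny-loss rate
#'
#' Under an exponential decay of synteny over divergence time, the per-MY
#' loss rate implied by observing proportion synteny `p_s` at divergence
#' time `T` is `1 - p_s^(1/T)`.
#'
#' @param p_s proportion synteny in (0, 1]; `p_s = 0` returns 1 (total
#'   loss) with a warning.
#' @param T divergence time in MY (> 0); by convention the age of the
#'   species pair's most recent common ancestor.
#' @return loss rate per MY in [0, 1]; vectorized over `p_s` and `T`.
#' @examples
#' loss_rate(0.81, 2)  # 0.1
#' @export
loss_rate <- function(p_s, T) {
  if (any(!is.finite(p_s)) || any(p_s < 0) || any(p_s > 1))
    stop_invalid("p_s must be in [0, 1]")
  if (any(!is.finite(T)) || any(T <= 0))
    stop_invalid("T must be > 0")
  if (any(p_s == 0))
    warning("p_s = 0: no surviving synteny; loss rate reported as 1")
  ifelse(p_s == 0, 1, 1 - p_s^(1 / T))
}

#' Synteny summary for one species pair
#'
#' Convenience wrapper chaining [detect_blocks()], [synteny_proportion()]
#' and [loss_rate()].
#'
#' @inheritParams detect_blocks
#' @param T divergence time in MY.
#' @return a `synteny_stats` list: `n_anchors`, `n_in_blocks`, `p_s`, `T`,
#'   `rate`.
#' @export
synteny_stats <- function(ga, gb, pairs, T, min_genes = 5, max_gap = 4,
                          max_inversions = 5) {
  blocks <- detect_blocks(ga, gb, pairs, min_genes, max_gap, max_inversions)
  p_s <- synteny_proportion(blocks, pairs)
  structure(list(n_anchors = attr(blocks, "n_anchors_total"),
                 n_in_blocks = sum(vapply(blocks, nrow, 1L)),
                 p_s = p_s, T = T,
                 rate = loss_rate(p_s, T)),
            class = "synteny_stats")
}

#' @export
print.synteny_stats <- function(x, ...) {
  cat(sprintf(
    "synteny_stats: %d/%d anchors in blocks; p_s = %.4f; T = %g MY; loss rate = %.5f /MY\n",
    x$n_in_blocks, x$n_anchors, x$p_s, x$T, x$rate))
  invisible(x)
}

#' Pairwise synteny-loss and rate matrices for a set of species
#'
#' For every unordered species pair, computes `p_s` from the pair's
#' orthologues and annotations and converts it to a loss distance
#' `1 - p_s` and a per-MY rate `1 - p_s^(1/T)`.  `T` is taken from the
#' dated tree as the age of the pair's MRCA (the literal reading of
#' divergence time); set `t_convention = "path_length"` to use the
#' tip-to-tip path `2T` instead.
#'
#' @param genomes named list of annotations (names = tip labels).
#' @param pairsets named list of pair sets, named `"A__B"` (either
#'   orientation accepted; `gene_a` must belong to the first-named
#'   species).
#' @param tree dated `ape::phylo` containing every species.
#' @inheritParams detect_blocks
#' @param t_convention `"mrca_age"` (default) or `"path_length"`.
#' @return list with symmetric matrices `p_s`, `loss` (= 1 - p_s) and
#'   `rate`, all with zero diagonals.
#' @export
pairwise_loss_matrix <- function(genomes, pairsets, tree, min_genes = 5,
                                 max_gap = 4, max_inversions = 5,
                                 t_convention = c("mrca_age",
                                                  "path_length")) {
  t_convention <- match.arg(t_convention)
  species <- names(genomes)
  if (!all(species %in% tree$tip.label))
    stop_invalid("species missing from tree: ",
                 paste(setdiff(species, tree$tip.label), collapse = ", "))
  idx <- lapply(genomes, order_genes)
  n <- length(species)
  P <- matrix(1, n, n, dimnames = list(species, species))
  R <- matrix(0, n, n, dimnames = list(species, species))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- species[i]; b <- species[j]
    pr <- fetch_pairset(pairsets, a, b)
    st <- synteny_stats(idx[[a]], idx[[b]], pr,
                        T = mrca_age(tree, a, b) *
                          (if (t_convention == "path_length") 2 else 1),
                        min_genes, max_gap, max_inversions)
    P[i, j] <- P[j, i] <- st$p_s
    R[i, j] <- R[j, i] <- st$rate
  }
  list(p_s = P, loss = 1 - P, rate = R)
}

# look up a pairset under "A__B" or "B__A", re-orienting if needed
fetch_pairset <- function(pairsets, a, b) {
  key <- paste0(a, "__", b); rkey <- paste0(b, "__", a)
  if (!is.null(pairsets[[key]])) return(pairsets[[key]])
  if (!is.null(pairsets[[rkey]])) {
    p <- pairsets[[rkey]]
    out <- data.frame(gene_a = p$gene_b, gene_b = p$gene_a,
                      stringsAsFactors = FALSE)
    attr(out, "species") <- c(a, b)
    return(out)
  }
  stop_invalid("no pairset for species pair ", a, " / ", b)
}
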