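#' Reciprocal-best-hit one-to-one orthologue pairs
#'
#' For each query gene the best subject is the hit with maximal bit score
#' among hits passing the e-value cutoff, breaking ties by lower e-value and
#' then by lexicographically smallest subject id (a deterministic order the
#' underlying search tools do not guarantee).  A pair (a, b) is returned iff
#' b is best for a in the A->B table and a is best for b in the B->A table;
#' the result is one-to-one by construction.  Multiple HSPs for one gene
#' pair are collapsed to the max-bit-score row first.
#'
#' @param hits_ab,hits_ba outfmt-6 style hit tables for the two directions
#'   of one species pair (see [read_hit_table()]); if both carry a
#'   `species` attribute the pair identities are checked.
#' @param evalue_max e-value cutoff; hits with `evalue >= evalue_max` are
#'   ignored (default `1e-5`).
#' @param min_len_frac optional minimum alignment length as a fraction of
#'   the longer reported alignment for that query; `NULL` (default)
#'   disables the filter.
#' @return an `ortholog_pairs` object: data.frame with columns `gene_a`,
#'   `gene_b` and a `species` attribute `c(A, B)` when known.
#' @examples
#' ab <- data.frame(qseqid = "a1", sseqid = c("b1", "b2"),
#'                  evalue = 1e-9, bitscore = c(200, 150))
#' ba <- data.frame(qseqid = c("b1", "b2"), sseqid = "a1",
#'                  evalue = 1e-9, bitscore = c(190, 100))
#' rbh_pairs(ab, ba)  # a1 -- b1
#' @export
rbh_pairs <- function(hits_ab, hits_ba, evalue_max = 1e-5,
                      min_len_frac = NULL) {
  sp_ab <- attr(hits_ab, "species"); sp_ba <- attr(hits_ba, "species")
  if (!is.null(sp_ab) && !is.null(sp_ba) &&
      !identical(sp_ab, rev(sp_ba)))
    stop_invalid("hit tables are not reciprocal directions of one pair")
  best_ab <- best_hits(hits_ab, evalue_max, min_len_frac)
  best_ba <- best_hits(hits_ba, evalue_max, min_len_frac)
  m <- match(best_ab$sseqid, best_ba$qseqid)
  ok <- !is.na(m) & best_ba$sseqid[m] == best_ab$qseqid
  out <- data.frame(gene_a = best_ab$qseqid[ok],
                    gene_b = best_ab$sseqid[ok],
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(sp_ab)) attr(out, "species") <- sp_ab
  class(out) <- c("ortholog_pairs", "data.frame")
  out
}

# best subject per query after the e-value (and optional length) filter
best_hits <- function(hits, evalue_max, min_len_frac = NULL) {
  if (nrow(hits) == 0L)
    return(data.frame(qseqid = character(), sseqid = character()))
  h <- hits[hits$evalue < evalue_max, , drop = FALSE]
  if (!is.null(min_len_frac) && nrow(h)) {
    mx <- stats::ave(h$length, h$qseqid, FUN = max)
    h <- h[h$length >= min_len_frac * mx, , drop = FALSE]
  }
  if (nrow(h) == 0L)
    return(data.frame(qseqid = character(), sseqid = character()))
  # collapse multiple HSPs of one (q, s) pair to the strongest
  h <- h[order(h$qseqid, h$sseqid, -h$bitscore, h$evalue), , drop = FALSE]
  h <- h[!duplicated(h[c("qseqid", "sseqid")]), , drop = FALSE]
  h <- h[order(h$qseqid, -h$bitscore, h$evalue, h$sseqid), , drop = FALSE]
  h[!duplicated(h$qseqid), c("qseqid", "sseqid"), drop = FALSE]
}

#' Assemble one-to-one orthologue groups from pairwise links
#'
#' Builds a graph whose vertices are (species, gene) pairs and whose edges
#' are the pairwise one-to-one links, then takes connected components.
#' Components containing two or more genes from any one species are
#' discarded (and counted); with `require_all = TRUE` only components with
#' exactly one gene from every species are kept.
#'
#' @param pairsets list of [rbh_pairs()] results, each with a `species`
#'   attribute.
#' @param species character vector of all species considered.
#' @param require_all keep only groups spanning every species (default
#'   TRUE).
#' @return list of groups, each a named character vector species -> gene
#'   id; attribute `n_discarded` counts components dropped for having >1
#'   gene in some species.
#' @export
build_one2one_groups <- function(pairsets, species, require_all = TRUE) {
  edges <- lapply(pairsets, function(p) {
    sp <- attr(p, "species")
    if (is.null(sp)) stop_invalid("pairset lacks species attribute")
    if (!all(sp %in% species))
      stop_invalid("pairset species not in species list")
    if (nrow(p) == 0L) return(NULL)
    cbind(paste0(sp[1], "\r", p$gene_a), paste0(sp[2], "\r", p$gene_b))
  })
  edges <- do.call(rbind, edges)
  if (is.null(edges) || nrow(edges) == 0L) {
    out <- list(); attr(out, "n_discarded") <- 0L; return(out)
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  comp <- igraph::components(g)
  members <- split(igraph::V(g)$name, comp$membership)
  n_disc <- 0L
  groups <- list()
  for (mm in members) {
    sp <- sub("\r.*$", "", mm)
    gene <- sub("^.*\r", "", mm)
    if (anyDuplicated(sp)) { n_disc <- n_disc + 1L; next }
    if (require_all && !setequal(sp, species)) next
    if (length(mm) < 2L) next
    groups[[length(groups) + 1L]] <- setNames(gene, sp)[order(sp)]
  }
  attr(groups, "n_discarded") <- n_disc
  groups
}
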