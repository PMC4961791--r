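#' Configuration for the genome-rearrangement simulator
#'
#' Rates are per million years along each branch of the dated tree:
#' `inversion_rate` and `translocation_rate` are genome-wide event rates,
#' `gene_loss_rate` is per gene (so the expected number of losses on a branch
#' is `rate * branch_MY * n_genes`), and `gene_gain_rate` is genome-wide.
#' Segment lengths for inversions and translocations follow a geometric
#' distribution on 1, 2, ... with mean `span_mean` genes, truncated at the
#' scaffold end; small rearrangements therefore dominate.
#'
#' @param n_scaffolds number of scaffolds in the ancestral genome.
#' @param n_genes total ancestral gene count (>= n_scaffolds).
#' @param inversion_rate,translocation_rate genome-wide events / MY.
#' @param gene_loss_rate per-gene losses / MY.
#' @param gene_gain_rate genome-wide gains / MY.
#' @param span_mean mean rearranged-segment length in genes (default 5).
#' @param seed master integer seed; each branch of the tree receives its own
#'   stream derived from it, so edits elsewhere in a configuration do not
#'   perturb a branch's events.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_scaffolds, n_genes,
                       inversion_rate = 0, translocation_rate = 0,
                       gene_loss_rate = 0, gene_gain_rate = 0,
                       span_mean = 5, seed = 1L) {
  rates <- c(inversion_rate, translocation_rate, gene_loss_rate,
             gene_gain_rate)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop_invalid("all rates must be finite and non-negative")
  if (n_genes < n_scaffolds)
    stop_invalid("n_genes must be >= n_scaffolds")
  if (span_mean < 1) stop_invalid("span_mean must be >= 1")
  structure(list(n_scaffolds = as.integer(n_scaffolds),
                 n_genes = as.integer(n_genes),
                 inversion_rate = inversion_rate,
                 translocation_rate = translocation_rate,
                 gene_loss_rate = gene_loss_rate,
                 gene_gain_rate = gene_gain_rate,
                 span_mean = span_mean,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# ---- internal genome representation -------------------------------------
# a genome is a list of scaffolds; each scaffold is list(ids, strand) with
# strand coded +1/-1.  Only gene order and strand matter; coordinates are
# re-emitted at the end.

ancestral_genome <- function(cfg) {
  ids <- sprintf("g%05d", seq_len(cfg$n_genes))
  cut <- sort(rep_len(seq_len(cfg$n_scaffolds), cfg$n_genes))
  lapply(split(ids, cut), function(x) list(ids = x,
                                           strand = rep(1L, length(x))))
}

genome_size <- function(gen) sum(vapply(gen, function(s) length(s$ids), 1L))

# pick (scaffold, position) uniformly over genes
pick_gene <- function(gen) {
  counts <- vapply(gen, function(s) length(s$ids), 1L)
  s <- sample.int(length(gen), 1L, prob = counts)
  list(s = s, i = sample.int(counts[s], 1L))
}

draw_span <- function(cfg, max_len) {
  min(1L + stats::rgeom(1L, 1 / cfg$span_mean), max_len)
}

apply_inversion <- function(gen, cfg) {
  if (genome_size(gen) == 0L) return(gen)
  p <- pick_gene(gen)
  sc <- gen[[p$s]]
  span <- draw_span(cfg, length(sc$ids) - p$i + 1L)
  idx <- p$i:(p$i + span - 1L)
  sc$ids[idx] <- rev(sc$ids[idx])
  sc$strand[idx] <- -rev(sc$strand[idx])
  gen[[p$s]] <- sc
  gen
}

apply_translocation <- function(gen, cfg) {
  if (genome_size(gen) == 0L) return(gen)
  p <- pick_gene(gen)
  sc <- gen[[p$s]]
  span <- draw_span(cfg, length(sc$ids) - p$i + 1L)
  idx <- p$i:(p$i + span - 1L)
  seg <- list(ids = sc$ids[idx], strand = sc$strand[idx])
  sc$ids <- sc$ids[-idx]; sc$strand <- sc$strand[-idx]
  gen[[p$s]] <- sc
  t <- sample.int(length(gen), 1L)
  tg <- gen[[t]]
  pos <- sample.int(length(tg$ids) + 1L, 1L) - 1L   # insert after `pos`
  tg$ids <- append(tg$ids, seg$ids, after = pos)
  tg$strand <- append(tg$strand, seg$strand, after = pos)
  gen[[t]] <- tg
  gen
}

apply_loss <- function(gen) {
  if (genome_size(gen) == 0L) return(gen)
  p <- pick_gene(gen)
  gen[[p$s]]$ids <- gen[[p$s]]$ids[-p$i]
  gen[[p$s]]$strand <- gen[[p$s]]$strand[-p$i]
  gen
}

apply_gain <- function(gen, new_id) {
  counts <- vapply(gen, function(s) length(s$ids), 1L)
  s <- sample.int(length(gen), 1L, prob = counts + 1L)
  pos <- sample.int(counts[s] + 1L, 1L) - 1L
  gen[[s]]$ids <- append(gen[[s]]$ids, new_id, after = pos)
  gen[[s]]$strand <- append(gen[[s]]$strand, sample(c(1L, -1L), 1L),
                            after = pos)
  gen
}

# evolve a genome along one branch; returns list(genome, log rows)
evolve_branch <- function(gen, cfg, t, branch_key) {
  log <- list()
  withr::with_seed(stream_seed(cfg$seed, paste0("branch:", branch_key)), {
    n0 <- genome_size(gen)
    n_ev <- c(inv  = stats::rpois(1L, cfg$inversion_rate * t),
              tra  = stats::rpois(1L, cfg$translocation_rate * t),
              loss = stats::rpois(1L, cfg$gene_loss_rate * t * n0),
              gain = stats::rpois(1L, cfg$gene_gain_rate * t))
    evs <- rep(names(n_ev), n_ev)
    if (length(evs) > 1L) evs <- sample(evs)
    gain_i <- 0L
    for (ev in evs) {
      gen <- switch(ev,
        inv  = apply_inversion(gen, cfg),
        tra  = apply_translocation(gen, cfg),
        loss = apply_loss(gen),
        gain = {
          gain_i <- gain_i + 1L
          apply_gain(gen, sprintf("x_%s_%03d", branch_key, gain_i))
        })
      log[[length(log) + 1L]] <- data.frame(branch = branch_key, type = ev,
                                            stringsAsFactors = FALSE)
    }
  })
  list(genome = gen, log = log)
}

# emit a genome as an annotation table: 1 kb genes, 100 bp spacers, 1-based
emit_annotation <- function(gen, species) {
  rows <- lapply(seq_along(gen), function(j) {
    sc <- gen[[j]]
    n <- length(sc$ids)
    if (n == 0L) return(NULL)
    start <- (seq_len(n) - 1L) * 1100L + 1L
    data.frame(gene_id = paste0(species, ".", sc$ids),
               scaffold = sprintf("S%02d", j),
               start = start, end = start + 999L,
               strand = ifelse(sc$strand > 0, "+", "-"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate gene orders evolving along a dated tree
#'
#' An ancestral genome of `cfg$n_genes` genes on `cfg$n_scaffolds` scaffolds
#' evolves down every branch of `tree`.  Event counts per branch are Poisson
#' with mean rate x branch duration; events are applied in random order.
#' Inversions reverse a contiguous segment and flip strands, translocations
#' move a segment to a uniformly chosen position (possibly another scaffold),
#' losses delete single genes, and gains insert novel genes with fresh ids
#' (which never receive similarity hits downstream).  Each branch uses an
#' RNG stream derived from `cfg$seed` and the branch identity, so results
#' are reproducible branch by branch.
#'
#' @param tree a dated `ape::phylo` from [simulate_tree()] or equivalent.
#' @param cfg a [sim_config()].
#' @return list with elements
#'   * `genomes`: named list of annotation data.frames (gene_id, scaffold,
#'     start, end, strand), one per tip;
#'   * `truth`: a `truth_set` with `ortholog_map` (data.frame: `ancestor`
#'     plus one column per species; NA where the gene was lost) and
#'     `event_log`.
#' @export
simulate_genomes <- function(tree, cfg) {
  stopifnot(inherits(tree, "phylo"), inherits(cfg, "sim_config"))
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  genomes <- vector("list", ntip + tree$Nnode)
  genomes[[root]] <- ancestral_genome(cfg)
  log <- list()
  # preorder over edges (parents before children in ape post-reorder)
  edges <- ape::reorder.phylo(tree, "cladewise")$edge
  lens  <- ape::reorder.phylo(tree, "cladewise")$edge.length
  for (k in seq_len(nrow(edges))) {
    par <- edges[k, 1L]; chi <- edges[k, 2L]
    key <- if (chi <= ntip) tree$tip.label[chi] else paste0("n", chi)
    res <- evolve_branch(genomes[[par]], cfg, lens[k], key)
    genomes[[chi]] <- res$genome
    log <- c(log, res$log)
  }
  species <- tree$tip.label
  out <- setNames(lapply(seq_len(ntip), function(i)
    emit_annotation(genomes[[i]], species[i])), species)
  anc_ids <- sprintf("g%05d", seq_len(cfg$n_genes))
  omap <- data.frame(ancestor = anc_ids, stringsAsFactors = FALSE)
  for (i in seq_len(ntip)) {
    surv <- unlist(lapply(genomes[[i]], `[[`, "ids"))
    omap[[species[i]]] <- ifelse(anc_ids %in% surv,
                                 paste0(species[i], ".", anc_ids), NA)
  }
  truth <- structure(list(ortholog_map = omap,
                          event_log = if (length(log))
                            do.call(rbind, log)
                          else data.frame(branch = character(),
                                          type = character())),
                     class = "truth_set")
  list(genomes = out, truth = truth)
}
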