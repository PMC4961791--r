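#' Simulate BLAST-style similarity hit tables for every ordered species pair
#'
#' Every surviving orthologue pair from the truth set receives a
#' high-scoring hit in both directions (bit score drawn in 250-500, well
#' above the paralog range).  With probability `noise` per orthologous query
#' gene, a spurious paralog hit to a random subject gene is added with a
#' strictly lower bit score (60-180), so spurious hits can never outscore a
#' true hit.  E-values are a fixed decreasing function of bit score
#' (`10^(-score/10)`), hence anti-monotone with score across the whole
#' table.  Novel (gained) genes have no homologues and receive no hits.
#'
#' @param genomes named list of annotation data.frames (from
#'   [simulate_genomes()]).
#' @param truth the matching `truth_set`.
#' @param noise per-gene probability of one spurious paralog hit, in [0,1].
#' @param seed integer seed; each ordered pair uses a derived stream.
#' @return named list of hit tables, one per ordered pair, named
#'   `"A__B"`; each is a 12-column BLAST outfmt-6 style data.frame
#'   (qseqid, sseqid, pident, length, mismatch, gapopen, qstart, qend,
#'   sstart, send, evalue, bitscore) with a `species` attribute `c(A, B)`.
#' @export
simulate_hit_table <- function(genomes, truth, noise = 0, seed = 1L) {
  if (!is.numeric(noise) || noise < 0 || noise > 1)
    stop_invalid("noise must be in [0, 1]")
  species <- names(genomes)
  omap <- truth$ortholog_map
  out <- list()
  for (a in species) for (b in species) {
    if (a == b) next
    keep <- !is.na(omap[[a]]) & !is.na(omap[[b]])
    qa <- omap[[a]][keep]; sb <- omap[[b]][keep]
    key <- paste0(a, "__", b)
    tab <- withr::with_seed(stream_seed(seed, paste0("hits:", key)), {
      n <- length(qa)
      bs <- runif(n, 250, 500)
      true_hits <- outfmt6_rows(qa, sb, bs, pid_lo = 80)
      n_sp <- stats::rbinom(1L, n, noise)
      if (n_sp > 0L && n > 0L) {
        qi <- sample.int(n, n_sp)
        sj <- sample(genomes[[b]]$gene_id, n_sp, replace = TRUE)
        sp_hits <- outfmt6_rows(qa[qi], sj, runif(n_sp, 60, 180),
                                pid_lo = 40)
        rbind(true_hits, sp_hits)
      } else true_hits
    })
    attr(tab, "species") <- c(a, b)
    out[[key]] <- tab
  }
  out
}

# build outfmt-6 rows from query/subject ids and bit scores
outfmt6_rows <- function(q, s, bitscore, pid_lo) {
  n <- length(q)
  len <- if (n) sample(200:1000, n, replace = TRUE) else integer()
  pident <- round(runif(n, pid_lo, pid_lo + 20), 1)
  data.frame(qseqid = q, sseqid = s, pident = pident, length = len,
             mismatch = as.integer(round(len * (100 - pident) / 100)),
             gapopen = if (n) sample(0:3, n, replace = TRUE) else integer(),
             qstart = rep(1L, n), qend = len, sstart = rep(1L, n),
             send = len, evalue = 10^(-bitscore / 10),
             bitscore = round(bitscore, 1), stringsAsFactors = FALSE)
}
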