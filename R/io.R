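# Readers / writers for the plain-text interchange formats used by the
# pipeline.  Comment lines starting with '#' carry provenance metadata and
# are skipped on read.

meta_header <- function(meta) {
  if (is.null(meta)) return(character())
  paste0("# ", names(meta), ": ", unlist(meta))
}

write_tsv_meta <- function(df, path, meta = NULL, col.names = TRUE) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta_header(meta), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = col.names)
}

#' Write / read a gene annotation as 5-column TSV
#'
#' Columns: gene_id, scaffold, start, end, strand (+/-); 1-based inclusive
#' coordinates.  Lines starting with `#` are metadata.
#'
#' @param g annotation data.frame.
#' @param path file path.
#' @param meta optional named list written as `# key: value` header lines.
#' @export
write_genome_tsv <- function(g, path, meta = NULL) {
  check_annotation(g)
  write_tsv_meta(g[c("gene_id", "scaffold", "start", "end", "strand")],
                 path, meta)
}

#' @rdname write_genome_tsv
#' @export
read_genome_tsv <- function(path) {
  g <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                  colClasses = c("character", "character", "integer",
                                 "integer", "character"))
  check_annotation(g)
  g
}

#' Write / read a hit table in BLAST tabular (outfmt 6) layout
#'
#' 12 unnamed columns: qseqid sseqid pident length mismatch gapopen qstart
#' qend sstart send evalue bitscore.
#'
#' @param hits hit-table data.frame.
#' @param path file path.
#' @param meta optional metadata written as `#` comment lines.
#' @export
write_hit_table <- function(hits, path, meta = NULL) {
  write_tsv_meta(hits[OUTFMT6_COLS], path, meta, col.names = FALSE)
}

OUTFMT6_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send",
                  "evalue", "bitscore")

#' @rdname write_hit_table
#' @param species optional `c(query_species, subject_species)` attached as
#'   an attribute.
#' @export
read_hit_table <- function(path, species = NULL) {
  h <- read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                  col.names = OUTFMT6_COLS,
                  colClasses = c("character", "character", rep("numeric", 10)))
  if (!is.null(species)) attr(h, "species") <- species
  h
}

#' Write / read an orthologue pair set as TSV
#'
#' @param pairs an [rbh_pairs()] result.
#' @param path file path.
#' @param meta optional metadata lines.
#' @export
write_pairs_tsv <- function(pairs, path, meta = NULL) {
  sp <- attr(pairs, "species")
  if (!is.null(sp)) meta <- c(meta, list(species = paste(sp, collapse = ",")))
  write_tsv_meta(as.data.frame(pairs), path, meta)
}

#' @rdname write_pairs_tsv
#' @export
read_pairs_tsv <- function(path) {
  first <- readLines(path, n = 5L)
  sp <- sub("^# species: ", "", grep("^# species: ", first, value = TRUE))
  p <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                  colClasses = "character")
  if (length(sp)) attr(p, "species") <- strsplit(sp[1], ",")[[1]]
  class(p) <- c("ortholog_pairs", "data.frame")
  p
}

#' Write / read a PHYLIP square distance matrix
#'
#' Relaxed PHYLIP: first line is the number of taxa; each following line
#' is a name and the full row of distances.
#'
#' @param m symmetric numeric matrix with dimnames.
#' @param path file path.
#' @export
write_phylip_dist <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(m)), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(c(rownames(m)[i],
                       formatC(m[i, ], format = "g", digits = 10)),
                     collapse = "  "), con)
}

#' @rdname write_phylip_dist
#' @export
read_phylip_dist <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  parts <- strsplit(trimws(lines[1 + seq_len(n)]), "[[:space:]]+")
  nm <- vapply(parts, `[[`, "", 1L)
  m <- t(vapply(parts, function(p) as.numeric(p[-1L]), numeric(n)))
  dimnames(m) <- list(nm, nm)
  m
}
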