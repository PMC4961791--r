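# pK values of ionizable groups (EMBOSS pepstats table)
PK_TABLE <- c(Nterm = 8.6, Cterm = 3.6,
              K = 10.8, R = 12.5, H = 6.5,         # positive
              D = 3.9, E = 4.1, C = 8.5, Y = 10.1) # negative

# average residue masses, Da (monomer mass minus water)
RESIDUE_MASS <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
                  C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
                  H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
                  M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
                  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)

check_residues <- function(seq, on_invalid) {
  aa <- strsplit(toupper(seq), "")[[1]]
  bad <- !(aa %in% names(RESIDUE_MASS))
  if (any(bad)) {
    if (on_invalid == "error")
      stop_invalid("non-standard residue(s): ",
                   paste(unique(aa[bad]), collapse = ", "))
    aa <- aa[!bad]
  }
  aa
}

# net protein charge at a given pH (Henderson-Hasselbalch per group)
protein_charge <- function(aa, pH) {
  n_pos <- c(Nterm = 1, K = sum(aa == "K"), R = sum(aa == "R"),
             H = sum(aa == "H"))
  n_neg <- c(Cterm = 1, D = sum(aa == "D"), E = sum(aa == "E"),
             C = sum(aa == "C"), Y = sum(aa == "Y"))
  pos <- sum(n_pos / (1 + 10^(pH - PK_TABLE[names(n_pos)])))
  neg <- sum(n_neg / (1 + 10^(PK_TABLE[names(n_neg)] - pH)))
  pos - neg
}

#' Protein isoelectric point (pepstats-style)
#'
#' The net charge at a given pH sums, over the ionizable groups (free N
#' and C termini, K, R, H positive; D, E, C, Y negative),
#' `1 / (1 + 10^(pH - pK))` for bases and `-1 / (1 + 10^(pK - pH))` for
#' acids, using the EMBOSS pK table.  The pI is the root of the charge
#' curve on [0, 14], found by bisection to |charge| < 1e-6.
#'
#' @param seq amino-acid string over the 20 standard residues.
#' @param on_invalid `"error"` (default) or `"skip"` non-standard
#'   residues.
#' @return isoelectric point in pH units.
#' @examples
#' protein_pi("A")  # 6.1: midpoint of the terminal pKs
#' @export
protein_pi <- function(seq, on_invalid = c("error", "skip")) {
  on_invalid <- match.arg(on_invalid)
  aa <- check_residues(seq, on_invalid)
  lo <- 0; hi <- 14
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    ch <- protein_charge(aa, mid)
    if (abs(ch) < 1e-6) break
    if (ch > 0) lo <- mid else hi <- mid
  }
  mid
}

#' Average residue weight of a protein
#'
#' Mean of the standard average residue masses (amino-acid monomer mass
#' minus water) over the sequence, in Da per residue.
#'
#' @inheritParams protein_pi
#' @return mean residue mass in Da.
#' @examples
#' avg_residue_weight("G")  # 57.0519
#' @export
avg_residue_weight <- function(seq, on_invalid = c("error", "skip")) {
  on_invalid <- match.arg(on_invalid)
  aa <- check_residues(seq, on_invalid)
  if (!length(aa)) stop_invalid("empty sequence")
  mean(RESIDUE_MASS[aa])
}

#' Protein properties for a FASTA file of protein sequences
#'
#' @param path FASTA file of amino-acid sequences (requires the Biostrings
#'   package).
#' @param on_invalid passed to [protein_pi()] / [avg_residue_weight()].
#' @return data.frame: name, length, pI, avg_residue_weight.
#' @export
protein_properties <- function(path, on_invalid = "skip") {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop_invalid("protein_properties() requires the Biostrings package")
  seqs <- Biostrings::readAAStringSet(path)
  s <- as.character(seqs)
  data.frame(name = names(seqs), length = nchar(s),
             pI = vapply(s, protein_pi, 1, on_invalid = on_invalid,
                         USE.NAMES = FALSE),
             avg_residue_weight = vapply(s, avg_residue_weight, 1,
                                         on_invalid = on_invalid,
                                         USE.NAMES = FALSE),
             stringsAsFactors = FALSE)
}
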