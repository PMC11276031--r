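# Standard genetic code tables in the RNA alphabet, derived from
# Biostrings::GENETIC_CODE at install time so no codon assignment is hand-typed.

CODON_TO_AA <- local({
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(unname(gc), chartr("T", "U", names(gc)))
})

RNA_CODONS <- sort(names(CODON_TO_AA))

STOP_CODONS <- sort(names(CODON_TO_AA)[CODON_TO_AA == "*"])

#' @keywords internal
SENSE_CODONS <- sort(setdiff(RNA_CODONS, STOP_CODONS))

# the 59 codons belonging to degenerate (synonymous) families:
# all sense codons except AUG (Met) and UGG (Trp)
SYN_CODONS <- sort(setdiff(SENSE_CODONS, c("AUG", "UGG")))

START_CODON <- "AUG"

# Kyte-Doolittle hydropathy values, one-letter amino acid codes
KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
  L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

AROMATIC_AA <- c("F", "Y", "W")

#' Synonymous family assignment for the 61 sense codons
#'
#' Returns the degeneracy-family label of every sense codon under one of two
#' schemes. Under `"standard"` each amino acid is one family (Leu, Ser and
#' Arg are six-fold). Under `"split"` the three six-fold families are split
#' into a four-fold and a two-fold subfamily (Leu: CUN + UUR; Ser: UCN + AGY;
#' Arg: CGN + AGR), the scheme under which published genome-wide RSCU tables
#' for the lycophyte/fern genomes are reproduced.
#'
#' @param scheme `"split"` (default) or `"standard"`.
#' @return Named character vector mapping each sense codon (RNA alphabet) to
#'   its family label. Single-codon families (AUG, UGG) are included.
#' @examples
#' table(codon_families("standard"))["L"]  # 6 codons
#' codon_families("split")[c("CUU", "UUG")]
#' @export
codon_families <- function(scheme = c("split", "standard")) {
  scheme <- match.arg(scheme)
  fam <- CODON_TO_AA[SENSE_CODONS]
  if (scheme == "split") {
    six <- names(table(fam))[table(fam) == 6]
    idx <- fam %in% six
    # subfamily identified by the first two codon bases (CU/UU, UC/AG, CG/AG)
    fam[idx] <- paste0(fam[idx], "_", substr(names(fam)[idx], 1, 2))
  }
  fam
}

# family sizes for a family assignment vector
family_sizes <- function(fam) {
  tab <- table(fam)
  stats::setNames(as.integer(tab), names(tab))
}

# third-position base of each codon in a character vector
third_base <- function(codons) substr(codons, 3, 3)

is_gc_base <- function(bases) bases %in% c("G", "C")
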