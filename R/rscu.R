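#' Relative synonymous codon usage (RSCU)
#'
#' RSCU of codon j in a synonymous family i of size n_i with counts x_ij is
#' x_ij / ((1/n_i) * sum_j x_ij): the observed count relative to the count
#' expected under uniform usage within the family. RSCU > 1 marks a codon
#' used more often than expected (a high-frequency codon), RSCU < 1 less
#' often. Families with zero total count get `NA` (undefined, not zero).
#' Single-codon families (AUG, UGG) have RSCU identically 1.
#'
#' @param counts Named codon count vector (per gene or pooled); stop codons
#'   are ignored.
#' @param scheme Degeneracy-family scheme, see [codon_families()].
#' @return A tibble with columns `amino_acid`, `codon`, `family`, `count`,
#'   `rscu`, ordered by amino acid then codon; attribute `scheme` records
#'   the family scheme used.
#' @examples
#' counts <- c(GCA = 328432, GCC = 173863, GCG = 91978, GCU = 301610)
#' rscu(counts)$rscu[1]  # 1.466...
#' @export
rscu <- function(counts, scheme = c("split", "standard")) {
  scheme <- match.arg(scheme)
  x <- as_count_vector(counts)[SENSE_CODONS]
  fam <- codon_families(scheme)
  vals <- rscu_values(x, fam)
  out <- tibble::tibble(
    amino_acid = unname(CODON_TO_AA[SENSE_CODONS]),
    codon = SENSE_CODONS,
    family = unname(fam),
    count = unname(x),
    rscu = unname(vals)
  )
  out <- out[order(out$amino_acid, out$codon), ]
  attr(out, "scheme") <- scheme
  out
}

# RSCU for a named count vector over sense codons, given a family vector
rscu_values <- function(x, fam) {
  means <- stats::ave(x, fam, FUN = mean)
  out <- x / means
  out[means == 0] <- NA_real_
  out
}

#' Per-gene RSCU matrix
#'
#' Computes RSCU gene by gene from a count matrix. This is the input of the
#' correspondence analysis; note that the pooled-genome RSCU equals the RSCU
#' of the pooled counts, not the mean of the per-gene rows.
#'
#' @param counts Count matrix (genes x 64) from [codon_count_matrix()].
#' @param scheme Family scheme.
#' @param codons Which codons to return columns for; defaults to the 59
#'   synonymous codons (AUG/UGG dropped).
#' @return Numeric matrix genes x codons; `NA` where a gene has a zero
#'   family total.
#' @export
rscu_matrix <- function(counts, scheme = c("split", "standard"),
                        codons = SYN_CODONS) {
  scheme <- match.arg(scheme)
  fam <- codon_families(scheme)
  x <- counts[, SENSE_CODONS, drop = FALSE]
  out <- matrix(NA_real_, nrow(x), ncol(x), dimnames = dimnames(x))
  for (f in unique(fam)) {
    cols <- names(fam)[fam == f]
    m <- rowMeans(x[, cols, drop = FALSE])
    vals <- x[, cols, drop = FALSE] / m
    vals[m == 0, ] <- NA_real_
    out[, cols] <- vals
  }
  out[, codons, drop = FALSE]
}
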