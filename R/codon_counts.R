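#' Count in-frame codons of one CDS
#'
#' Counts every in-frame triplet of a CDS, including the start AUG, UGG and
#' the terminal stop codon. Downstream synonymous statistics exclude stop
#' codons themselves; keeping them in the count table preserves the
#' book-keeping identity that counts sum to length/3.
#'
#' @param seq RNA CDS string with length a multiple of 3.
#' @return Named integer vector over all 64 codons.
#' @examples
#' count_codons("AUGAAAUAA")[c("AUG", "AAA", "UAA")]
#' @export
count_codons <- function(seq) {
  codons <- split_codons(seq)
  bad <- setdiff(unique(codons), RNA_CODONS)
  if (length(bad)) stop("non-ACGU codon(s): ", paste(bad, collapse = ", "))
  tab <- table(factor(codons, levels = RNA_CODONS))
  stats::setNames(as.integer(tab), RNA_CODONS)
}

#' Per-gene codon count matrix
#'
#' @param genes Gene tibble (`id`, `seq`); sequences must be in frame.
#' @return Integer matrix, one row per gene (rownames = ids), 64 codon
#'   columns in alphabetical RNA order.
#' @export
codon_count_matrix <- function(genes) {
  mats <- vapply(genes$seq, function(s) count_codons(s),
                 integer(length(RNA_CODONS)), USE.NAMES = FALSE)
  out <- t(mats)
  dimnames(out) <- list(genes$id, RNA_CODONS)
  out
}

#' Pool per-gene codon counts over a genome
#'
#' @param counts Count matrix from [codon_count_matrix()] or a single named
#'   count vector.
#' @return Named integer vector over 64 codons (the column sums).
#' @export
pool_counts <- function(counts) {
  if (is.matrix(counts)) {
    stats::setNames(as.integer(colSums(counts)), colnames(counts))
  } else {
    counts
  }
}

# coerce a named count vector to the full 64-codon layout
as_count_vector <- function(counts) {
  stopifnot(!is.null(names(counts)))
  out <- stats::setNames(numeric(length(RNA_CODONS)), RNA_CODONS)
  known <- intersect(names(counts), RNA_CODONS)
  if (length(known) < length(counts)) {
    stop("unknown codon name(s): ",
         paste(setdiff(names(counts), RNA_CODONS), collapse = ", "))
  }
  out[known] <- counts[known]
  out
}
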