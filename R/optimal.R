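#' High-frequency codons (pooled RSCU > 1)
#'
#' @param rscu_table Tibble from [rscu()] on pooled genome counts.
#' @return Character vector of codons with RSCU strictly greater than 1;
#'   AUG and UGG (RSCU identically 1) never qualify.
#' @export
high_frequency_codons <- function(rscu_table) {
  sel <- !is.na(rscu_table$rscu) & rscu_table$rscu > 1 &
    !(rscu_table$codon %in% c("AUG", "UGG"))
  sort(rscu_table$codon[sel])
}

#' High- and low-expression gene groups by extreme ENC
#'
#' Splits genes into putative expression groups using ENC as the proxy:
#' by default, and following the extreme-ENC convention, the `fraction` of
#' genes with the *lowest* ENC (strongest bias) form the high-expression
#' group and the highest-ENC genes the low-expression group.
#' `direction = "literal"` inverts this, assigning highest ENC to the
#' high-expression group. Ties at the cutoffs are broken by gene id order,
#' so the grouping is deterministic; a warning is emitted when all ENC
#' values are equal.
#'
#' @param metrics Tibble with columns `id` and `enc`.
#' @param fraction Group fraction (default 0.10).
#' @param direction `"low_enc"` (default) or `"literal"`.
#' @return List of class `"expression_groups"`: `high`, `low` (gene id
#'   vectors of size `ceiling(fraction * N)`), `fraction`, `direction`.
#' @export
expression_groups <- function(metrics, fraction = 0.10,
                              direction = c("low_enc", "literal")) {
  direction <- match.arg(direction)
  ok <- !is.na(metrics$enc)
  ids <- metrics$id[ok]
  enc_val <- metrics$enc[ok]
  n <- length(ids)
  size <- ceiling(fraction * n)
  if (n < 2 * size || size < 1) {
    stop("too few genes (", n, ") to form two disjoint groups of fraction ",
         fraction)
  }
  if (length(unique(enc_val)) == 1) {
    warning("all ENC values equal; groups filled by gene id order")
  }
  low_enc <- ids[order(enc_val, ids)][seq_len(size)]
  rest <- ids[order(-enc_val, ids)]
  high_enc <- rest[!rest %in% low_enc][seq_len(size)]  # disjoint even on ties
  out <- list(
    high = if (direction == "low_enc") low_enc else high_enc,
    low = if (direction == "low_enc") high_enc else low_enc,
    fraction = fraction, direction = direction
  )
  class(out) <- "expression_groups"
  out
}

#' Optimal codon screen by delta-RSCU
#'
#' Computes RSCU separately from the pooled counts of the high- and
#' low-expression groups, their difference delta-RSCU = RSCU_high -
#' RSCU_low per codon, and flags as optimal the codons with delta-RSCU at
#' or above the threshold (inclusive), RSCU > 1 in the high-expression
#' group, and RSCU > 1 in the whole-genome pool (the high-frequency
#' condition).
#'
#' @param high_counts,low_counts Pooled codon count vectors of the two
#'   groups.
#' @param pooled_rscu Tibble from [rscu()] on the whole-genome pooled
#'   counts.
#' @param threshold Delta-RSCU cutoff (default 0.08).
#' @param scheme Family scheme (default `"split"`, consistent with the
#'   pooled RSCU tables).
#' @return Tibble with one row per synonymous codon: `amino_acid`, `codon`,
#'   `rscu_high`, `rscu_low`, `delta_rscu`, `high_frequency`, `optimal`.
#' @export
optimal_codons <- function(high_counts, low_counts, pooled_rscu,
                           threshold = 0.08, scheme = c("split", "standard")) {
  scheme <- match.arg(scheme)
  hi <- rscu(high_counts, scheme = scheme)
  lo <- rscu(low_counts, scheme = scheme)
  stopifnot(identical(hi$codon, lo$codon))
  hf <- high_frequency_codons(pooled_rscu)
  out <- tibble::tibble(
    amino_acid = hi$amino_acid,
    codon = hi$codon,
    rscu_high = hi$rscu,
    rscu_low = lo$rscu,
    delta_rscu = hi$rscu - lo$rscu,
    high_frequency = hi$codon %in% hf
  )
  out <- out[!(out$codon %in% c("AUG", "UGG")), ]
  out$optimal <- !is.na(out$delta_rscu) & out$delta_rscu >= threshold &
    !is.na(out$rscu_high) & out$rscu_high > 1 & out$high_frequency
  out
}

#' Codons shared across genomes
#'
#' Plain intersection of codon sets (e.g. per-species high-frequency or
#' optimal codon sets), with per-set tallies of A/U-ending versus C/G-ending
#' codons. Intersection is commutative and associative.
#'
#' @param sets Named list of >= 2 character vectors of codons.
#' @return List with `shared` (sorted intersection) and `endings` (tibble:
#'   set, n, n_au_ending, n_cg_ending).
#' @export
shared_codons <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2)
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  shared <- sort(Reduce(intersect, sets))
  endings <- dplyr::bind_rows(lapply(names(sets), function(nm) {
    tb <- third_base(sets[[nm]])
    tibble::tibble(set = nm, n = length(sets[[nm]]),
                   n_au_ending = sum(tb %in% c("A", "U")),
                   n_cg_ending = sum(tb %in% c("C", "G")))
  }))
  list(shared = shared, endings = endings)
}
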