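#' Published genome-wide codon counts for four lycophyte and fern species
#'
#' Pooled CDS codon counts reported for the genome annotations of
#' *Adiantum capillus-veneris* (`ac`), *Ceratopteris richardii* (`cr`),
#' *Diphasiastrum complanatum* (`dc`) and *Selaginella moellendorffii*
#' (`sm`): 61 rows (stop codons are not tallied), one count column per
#' species. These counts are the desk-scale input for reproducing the
#' published RSCU values and high-frequency codon bookkeeping.
#'
#' @return Tibble with columns `amino_acid`, `codon`, `ac`, `cr`, `dc`,
#'   `sm`.
#' @export
published_codon_counts <- function() {
  path <- system.file("extdata", "lycofern_codon_counts.tsv",
                      package = "cubkit", mustWork = TRUE)
  readr::read_tsv(path, col_types = "ccdddd")
}

#' Published RSCU values for the four species
#'
#' The RSCU values printed alongside [published_codon_counts()], kept as
#' character strings so the printed precision (2 or 3 decimals per cell) is
#' preserved for exact-reproduction checks.
#'
#' @return Tibble with columns `amino_acid`, `codon`, `ac`, `cr`, `dc`,
#'   `sm` (character).
#' @export
published_rscu <- function() {
  path <- system.file("extdata", "lycofern_published_rscu.tsv",
                      package = "cubkit", mustWork = TRUE)
  readr::read_tsv(path, col_types = "cccccc")
}

#' Published genome GC summary for the four species
#'
#' Genome-level positional GC percentages (GC1, GC2, GC3, GCall) and mean
#' ENC for the four species.
#'
#' @return Tibble with columns `species`, `gc1`, `gc2`, `gc3`, `gc_all`,
#'   `enc`.
#' @export
published_gc_content <- function() {
  path <- system.file("extdata", "lycofern_gc_content.tsv",
                      package = "cubkit", mustWork = TRUE)
  readr::read_tsv(path, col_types = "cddddd")
}
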