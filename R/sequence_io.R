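#' Read a nucleotide CDS FASTA file
#'
#' Parses a FASTA file of coding sequences into a gene table. Sequences are
#' whitespace-stripped, upper-cased and stored in the RNA alphabet (T is
#' converted to U) so codons read as RNA triplets throughout the package.
#'
#' @param path Path to a FASTA file (DNA or RNA alphabet).
#' @return A tibble with columns `id` (first whitespace-delimited token of
#'   the header), `seq` (RNA, upper case) and `length_nt`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">g1", "atg aaa", "taa"), fa)
#' parse_fasta(fa)
#' @export
parse_fasta <- function(path) {
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    stop("FASTA file contains no records: ", path, call. = FALSE)
  }
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate sequence id(s) in FASTA: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  seqs <- unname(toupper(gsub("\\s", "", as.character(set))))
  seqs <- chartr("T", "U", seqs)
  tibble::tibble(id = unname(ids), seq = seqs, length_nt = nchar(seqs))
}

#' Write a gene table to FASTA
#'
#' @param genes Gene tibble (`id`, `seq`).
#' @param path Output path.
#' @param alphabet `"DNA"` (default, U written as T) or `"RNA"`.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genes, path, alphabet = c("DNA", "RNA"), width = 70) {
  alphabet <- match.arg(alphabet)
  seqs <- genes$seq
  if (alphabet == "DNA") seqs <- chartr("U", "T", seqs)
  chunks <- lapply(seq_along(seqs), function(i) {
    s <- seqs[i]
    starts <- seq(1, nchar(s), by = width)
    c(paste0(">", genes$id[i]), substring(s, starts, pmin(starts + width - 1, nchar(s))))
  })
  writeLines(unlist(chunks), path)
  invisible(path)
}

# screening rules in fixed order; the reason code is the first failing rule
FILTER_REASONS <- c(
  "length_not_multiple_of_3", "length_lt_min", "invalid_base",
  "bad_start", "bad_stop", "internal_stop"
)

#' Screen coding sequences with the five CDS quality rules
#'
#' A CDS is kept iff all of the following hold, checked in this order:
#' length a multiple of 3; length at least `min_len` nucleotides (start and
#' stop included); alphabet restricted to A, C, G, U (ambiguity codes fail);
#' first codon AUG; last codon a stop (UAA, UAG, UGA); no in-frame internal
#' stop codon. Rejected sequences are reported with the first failing rule,
#' never dropped silently.
#'
#' @param genes Gene tibble from [parse_fasta()] (or [generate_genome()]).
#' @param min_len Minimum length in nucleotides (default 300).
#' @return A list of class `"filter_report"` with elements `kept` (gene
#'   tibble), `rejected` (gene tibble plus `reason` column) and
#'   `counts` (named integer vector over all reason codes).
#' @examples
#' g <- tibble::tibble(id = c("a", "b"),
#'                     seq = c(strrep("AUGAAA", 1), "AUGAA"),
#'                     length_nt = c(6, 5))
#' filter_cds(g, min_len = 6)$counts
#' @export
filter_cds <- function(genes, min_len = 300) {
  n <- nrow(genes)
  reason <- rep(NA_character_, n)
  len <- nchar(genes$seq)

  fail <- function(idx, code) {
    new <- idx & is.na(reason)
    reason[new] <<- code
  }
  fail(len %% 3 != 0, "length_not_multiple_of_3")
  fail(len < min_len, "length_lt_min")
  fail(grepl("[^ACGU]", genes$seq), "invalid_base")
  fail(substr(genes$seq, 1, 3) != START_CODON, "bad_start")
  fail(!(substr(genes$seq, len - 2, len) %in% STOP_CODONS), "bad_stop")
  internal_stop <- vapply(which(is.na(reason)), function(i) {
    body <- split_codons(substr(genes$seq[i], 1, len[i] - 3))
    any(body %in% STOP_CODONS)
  }, logical(1))
  fail(replace(logical(n), which(is.na(reason)), internal_stop), "internal_stop")

  counts <- stats::setNames(integer(length(FILTER_REASONS)), FILTER_REASONS)
  tab <- table(reason)
  counts[names(tab)] <- as.integer(tab)
  out <- list(
    kept = genes[is.na(reason), , drop = FALSE],
    rejected = dplyr::mutate(genes[!is.na(reason), , drop = FALSE],
                             reason = reason[!is.na(reason)]),
    counts = counts
  )
  class(out) <- "filter_report"
  out
}

#' @export
print.filter_report <- function(x, ...) {
  cat("CDS filter report: ", nrow(x$kept), " kept, ",
      nrow(x$rejected), " rejected\n", sep = "")
  shown <- x$counts[x$counts > 0]
  if (length(shown)) {
    for (r in names(shown)) cat("  ", r, ": ", shown[[r]], "\n", sep = "")
  }
  invisible(x)
}

#' Write the TSV rejection report of a CDS filter
#'
#' @param report A `filter_report` from [filter_cds()].
#' @param path Output TSV path (columns: id, length, reason).
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  tab <- tibble::tibble(
    id = report$rejected$id,
    length = nchar(report$rejected$seq),
    reason = report$rejected$reason
  )
  readr::write_tsv(tab, path)
  invisible(path)
}

# split an in-frame RNA string into codons
split_codons <- function(seq) {
  n <- nchar(seq)
  if (n == 0) return(character(0))
  if (n %% 3 != 0) stop("sequence length is not a multiple of 3")
  starts <- seq(1, n, by = 3)
  substring(seq, starts, starts + 2)
}

#' Translate an in-frame CDS to protein
#'
#' @param seq RNA CDS string (multiple of 3). A terminal stop codon, if
#'   present, is dropped; an internal stop is an error.
#' @return One-letter amino acid string.
#' @export
translate_cds <- function(seq) {
  codons <- split_codons(seq)
  if (length(codons) && codons[length(codons)] %in% STOP_CODONS) {
    codons <- codons[-length(codons)]
  }
  aa <- CODON_TO_AA[codons]
  if (anyNA(aa)) stop("unknown codon(s): ",
                      paste(unique(codons[is.na(aa)]), collapse = ", "))
  if (any(aa == "*")) stop("internal stop codon in CDS")
  paste(aa, collapse = "")
}
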