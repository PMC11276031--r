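#' Parse a Kazusa-style codon frequency table
#'
#' Reads the flat format of the Codon Usage Database: entries of the form
#' `UUU 21.8 ( 123)` (codon, frequency per 1000 codons, raw count), any
#' number per line, DNA or RNA spelling. A counts-only two-column variant
#' (`codon count`) is also accepted, with frequencies derived as
#' 1000 * count / total.
#'
#' @param x Path to a file, or the table text itself (character scalar or
#'   lines).
#' @param species Optional species label stored on the result.
#' @return A tibble of class `"frequency_table"` with columns `codon`
#'   (RNA, all 64), `freq_per_1000` and `count` (`NA` when not given).
#' @export
parse_kazusa <- function(x, species = NULL) {
  txt <- if (length(x) == 1 && file.exists(x)) readLines(x, warn = FALSE) else x
  txt <- paste(txt, collapse = "\n")
  full <- gregexpr("([ACGTUacgtu]{3})\\s+([0-9]*\\.?[0-9]+)\\s*\\(\\s*([0-9]+)\\s*\\)",
                   txt, perl = TRUE)
  m <- regmatches(txt, full)[[1]]
  if (length(m) > 0) {
    parts <- regmatches(m, regexec(
      "([ACGTUacgtu]{3})\\s+([0-9]*\\.?[0-9]+)\\s*\\(\\s*([0-9]+)\\s*\\)", m))
    codon <- vapply(parts, `[`, character(1), 2)
    freq <- as.numeric(vapply(parts, `[`, character(1), 3))
    count <- as.numeric(vapply(parts, `[`, character(1), 4))
  } else {
    two <- gregexpr("(?<![A-Za-z])([ACGTUacgtu]{3})\\s+([0-9]*\\.?[0-9]+)",
                    txt, perl = TRUE)
    m2 <- regmatches(txt, two)[[1]]
    if (length(m2) == 0) stop("no codon entries recognised in Kazusa input")
    parts <- regmatches(m2, regexec("([ACGTUacgtu]{3})\\s+([0-9]*\\.?[0-9]+)", m2))
    codon <- vapply(parts, `[`, character(1), 2)
    count <- as.numeric(vapply(parts, `[`, character(1), 3))
    freq <- 1000 * count / sum(count)
  }
  codon <- chartr("Tt", "Uu", toupper(codon))
  codon <- chartr("t", "u", codon)
  if (anyDuplicated(codon)) {
    stop("duplicate codon(s) in Kazusa input: ",
         paste(unique(codon[duplicated(codon)]), collapse = ", "))
  }
  missing <- setdiff(RNA_CODONS, codon)
  if (length(missing)) {
    stop("Kazusa table is missing codon(s): ", paste(missing, collapse = ", "))
  }
  ord <- match(RNA_CODONS, codon)
  out <- tibble::tibble(codon = RNA_CODONS, freq_per_1000 = freq[ord],
                        count = count[ord])
  class(out) <- c("frequency_table", class(out))
  attr(out, "species") <- species
  out
}

#' Codon frequency table from pooled genome counts
#'
#' @param counts Named 64-codon count vector (pooled over a genome).
#' @param species Optional species label.
#' @return A `frequency_table` tibble (frequencies per 1000 codons).
#' @export
frequency_table <- function(counts, species = NULL) {
  x <- as_count_vector(counts)
  out <- tibble::tibble(codon = RNA_CODONS,
                        freq_per_1000 = 1000 * unname(x) / sum(x),
                        count = unname(x))
  class(out) <- c("frequency_table", class(out))
  attr(out, "species") <- species
  out
}

#' Write a frequency table in Kazusa flat format
#'
#' @param ft A `frequency_table` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kazusa <- function(ft, path) {
  lines <- vapply(seq_len(nrow(ft)), function(i) {
    sprintf("%s %5.1f (%7d)", ft$codon[i], ft$freq_per_1000[i],
            as.integer(ft$count[i]))
  }, character(1))
  # four entries per line, as the Codon Usage Database prints them
  grp <- ceiling(seq_along(lines) / 4)
  writeLines(vapply(split(lines, grp), paste, character(1), collapse = "  "), path)
  invisible(path)
}

#' Codon usage ratio comparison between two species
#'
#' Per-codon ratio of usage frequencies (per 1000 codons) of two genomes.
#' Codons whose ratio is >= 2 or <= 0.5 (inclusive) are flagged as
#' divergent; a codon used by `a` but absent from `b` is flagged with an
#' infinite ratio, and a codon absent from both has an undefined ratio and
#' is not flagged. The summary counts flags among the 59 synonymous codons
#' only (stop codons are excluded; AUG and UGG are reported in the table
#' but marked non-synonymous), and the verdict is `"similar"` iff no
#' synonymous codon is flagged.
#'
#' @param a,b `frequency_table` tibbles (see [parse_kazusa()],
#'   [frequency_table()]).
#' @return List of class `"ratio_report"`: `table` (codon, freq_a, freq_b,
#'   ratio, synonymous, flagged), `n_flagged`, `verdict`.
#' @export
usage_ratio <- function(a, b) {
  stopifnot(identical(a$codon, b$codon))
  ratio <- ifelse(b$freq_per_1000 > 0, a$freq_per_1000 / b$freq_per_1000,
                  ifelse(a$freq_per_1000 > 0, Inf, NA_real_))
  tab <- tibble::tibble(
    codon = a$codon,
    freq_a = a$freq_per_1000,
    freq_b = b$freq_per_1000,
    ratio = ratio,
    synonymous = a$codon %in% SYN_CODONS,
    flagged = !is.na(ratio) & (ratio >= 2 | ratio <= 0.5)
  )
  n_flagged <- sum(tab$flagged & tab$synonymous)
  out <- list(table = tab, n_flagged = n_flagged,
              verdict = if (n_flagged == 0) "similar" else "divergent",
              species = c(attr(a, "species") %||% "a",
                          attr(b, "species") %||% "b"))
  class(out) <- "ratio_report"
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.ratio_report <- function(x, ...) {
  cat("Codon usage comparison ", x$species[1], " vs ", x$species[2], ": ",
      x$n_flagged, " of 59 synonymous codons flagged (ratio >= 2 or <= 0.5) -> ",
      x$verdict, "\n", sep = "")
  invisible(x)
}
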