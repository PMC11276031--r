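# coerce count input (named vector or matrix) to a 1+ row matrix over 64 codons
as_count_matrix <- function(counts) {
  if (is.matrix(counts)) {
    stopifnot(all(RNA_CODONS %in% colnames(counts)))
    counts[, RNA_CODONS, drop = FALSE]
  } else {
    matrix(as_count_vector(counts), nrow = 1, dimnames = list(NULL, RNA_CODONS))
  }
}

#' GC content by codon position
#'
#' G+C fraction among first, second and third codon positions of all sense
#' codons (stop codons excluded, AUG/UGG included), plus the derived
#' summaries GC12 = (GC1+GC2)/2 and GCall = (GC1+GC2+GC3)/3.
#'
#' @param counts Named 64-codon count vector, or a genes x 64 count matrix
#'   for per-gene results.
#' @return Tibble with columns `gc1`, `gc2`, `gc3`, `gc12`, `gc_all`, one
#'   row per input gene (one row for a vector input).
#' @export
positional_gc <- function(counts) {
  m <- as_count_matrix(counts)[, SENSE_CODONS, drop = FALSE]
  tot <- rowSums(m)
  if (any(tot == 0)) stop("no sense codons counted for some input")
  gc_at <- function(k) {
    sel <- is_gc_base(substr(SENSE_CODONS, k, k))
    rowSums(m[, sel, drop = FALSE]) / tot
  }
  gc1 <- gc_at(1); gc2 <- gc_at(2); gc3 <- gc_at(3)
  tibble::tibble(gc1 = gc1, gc2 = gc2, gc3 = gc3,
                 gc12 = (gc1 + gc2) / 2, gc_all = (gc1 + gc2 + gc3) / 3)
}

#' Base composition at synonymous (silent) third positions
#'
#' Restricted to codons of degenerate families (Met, Trp and stops
#' excluded). Following the CodonW convention, each base fraction uses as
#' denominator only the silent third positions at which that base is
#' possible, i.e. codons whose family has a member ending in that base; the
#' four fractions therefore need not sum to 1. `gc3s` is the plain G+C
#' fraction over all synonymous third positions.
#'
#' @param counts Named 64-codon count vector or genes x 64 matrix.
#' @param scheme Family scheme used to define "possible" bases (default
#'   standard amino-acid families, as in CodonW).
#' @return Tibble with columns `a3s`, `t3s`, `c3s`, `g3s`, `gc3s`.
#' @export
silent_site_composition <- function(counts, scheme = c("standard", "split")) {
  scheme <- match.arg(scheme)
  m <- as_count_matrix(counts)[, SYN_CODONS, drop = FALSE]
  tot <- rowSums(m)
  if (any(tot == 0)) stop("no synonymous codons counted for some input")
  fam <- codon_families(scheme)[SYN_CODONS]
  tb <- third_base(SYN_CODONS)
  frac <- function(base) {
    fams_with_base <- unique(fam[tb == base])
    possible <- fam %in% fams_with_base
    denom <- rowSums(m[, possible, drop = FALSE])
    num <- rowSums(m[, tb == base, drop = FALSE])
    ifelse(denom > 0, num / denom, NA_real_)
  }
  gc3s <- rowSums(m[, is_gc_base(tb), drop = FALSE]) / tot
  tibble::tibble(a3s = frac("A"), t3s = frac("U"), c3s = frac("C"),
                 g3s = frac("G"), gc3s = gc3s)
}

#' PR2 (parity rule 2) plot coordinates
#'
#' Third-position purine/pyrimidine balance per gene: abscissa
#' G3/(G3 + C3) and ordinate A3/(A3 + T3), computed over third positions of
#' sense codons excluding AUG and UGG (default) or over four-fold degenerate
#' families only. Under strand-symmetric mutation with no selection both
#' coordinates centre on 0.5.
#'
#' @param counts Named 64-codon count vector or genes x 64 matrix.
#' @param sites `"synonymous"` (default; all codons of degenerate families)
#'   or `"fourfold"` (third positions of four-fold families only).
#' @return Tibble with columns `x` (GC bias) and `y` (AU bias); `NA` where
#'   a denominator is zero.
#' @export
pr2_point <- function(counts, sites = c("synonymous", "fourfold")) {
  sites <- match.arg(sites)
  codons <- if (sites == "synonymous") SYN_CODONS else {
    fam <- codon_families("standard")
    sizes <- family_sizes(fam)
    names(fam)[sizes[fam] == 4]
  }
  m <- as_count_matrix(counts)[, codons, drop = FALSE]
  tb <- third_base(codons)
  base_sum <- function(b) rowSums(m[, tb == b, drop = FALSE])
  g3 <- base_sum("G"); c3 <- base_sum("C")
  a3 <- base_sum("A"); t3 <- base_sum("U")
  tibble::tibble(
    x = ifelse(g3 + c3 > 0, g3 / (g3 + c3), NA_real_),
    y = ifelse(a3 + t3 > 0, a3 / (a3 + t3), NA_real_)
  )
}
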