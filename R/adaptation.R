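#' Relative adaptiveness weights for CAI
#'
#' From a reference codon count table (typically pooled counts of a
#' highly-expressed gene set), the weight of codon j is its count divided by
#' the largest count in its synonymous family. Codons unobserved in the
#' reference while their family is observed get the conventional floor of
#' 0.01 so the geometric mean stays defined; families entirely absent from
#' the reference get `NA` and are skipped by [cai()].
#'
#' @param ref_counts Named codon count vector of the reference set.
#' @param scheme Family scheme (default `"split"`).
#' @param floor Weight substituted for zero-count codons (default 0.01).
#' @return Named numeric weight vector over the 59 synonymous codons.
#' @export
build_cai_weights <- function(ref_counts, scheme = c("split", "standard"),
                              floor = 0.01) {
  scheme <- match.arg(scheme)
  x <- as_count_vector(ref_counts)[SYN_CODONS]
  fam <- codon_families(scheme)[SYN_CODONS]
  fam_max <- stats::ave(x, fam, FUN = max)
  w <- ifelse(fam_max > 0, x / fam_max, NA_real_)
  w[!is.na(w) & w == 0] <- floor
  stats::setNames(w, SYN_CODONS)
}

#' Codon adaptation index (CAI)
#'
#' Geometric mean of the relative adaptiveness weights of a gene's codons,
#' over synonymous codons only (AUG, UGG and stops excluded). Computed in
#' the log domain; codons whose weight is undefined (family absent from the
#' reference) are skipped.
#'
#' @param counts Named 64-codon count vector or genes x 64 matrix.
#' @param weights Weight vector from [build_cai_weights()].
#' @return CAI value(s) in (0, 1].
#' @export
cai <- function(counts, weights) {
  m <- as_count_matrix(counts)[, SYN_CODONS, drop = FALSE]
  w <- weights[SYN_CODONS]
  usable <- !is.na(w)
  logw <- log(w[usable])
  n <- rowSums(m[, usable, drop = FALSE])
  ifelse(n > 0, exp(as.vector(m[, usable, drop = FALSE] %*% logw) / n), NA_real_)
}

#' Codon bias index (CBI) and frequency of optimal codons (Fop)
#'
#' Given a set of optimal codons, Fop = N_opt / N_tot over synonymous
#' codons, and CBI = (N_opt - N_rand) / (N_tot - N_rand) where N_rand is the
#' optimal count expected under uniform usage within each family (so CBI is
#' 0 for unbiased usage, 1 when only optimal codons are used, negative when
#' optimal codons are avoided).
#'
#' @param counts Named 64-codon count vector or genes x 64 matrix.
#' @param optimal Character vector of optimal codons (subset of the 59
#'   synonymous codons).
#' @param scheme Family scheme defining the uniform expectation.
#' @return Tibble with columns `cbi` and `fop`.
#' @export
cbi_fop <- function(counts, optimal, scheme = c("standard", "split")) {
  scheme <- match.arg(scheme)
  stopifnot(all(optimal %in% SYN_CODONS))
  m <- as_count_matrix(counts)[, SYN_CODONS, drop = FALSE]
  fam <- codon_families(scheme)[SYN_CODONS]
  sizes <- family_sizes(fam)
  n_tot <- rowSums(m)
  n_opt <- rowSums(m[, SYN_CODONS %in% optimal, drop = FALSE])
  # expected optimal count under uniform synonymous usage
  opt_per_fam <- table(factor(fam[SYN_CODONS %in% optimal], levels = names(sizes)))
  frac <- as.numeric(opt_per_fam) / as.numeric(sizes)
  fam_tot <- vapply(names(sizes), function(f)
    rowSums(m[, fam == f, drop = FALSE]), numeric(nrow(m)))
  fam_tot <- matrix(fam_tot, nrow = nrow(m))
  n_rand <- as.vector(fam_tot %*% frac)
  tibble::tibble(
    cbi = ifelse(n_tot - n_rand != 0, (n_opt - n_rand) / (n_tot - n_rand), NA_real_),
    fop = ifelse(n_tot > 0, n_opt / n_tot, NA_real_)
  )
}

#' Protein-level indices of a CDS
#'
#' Gravy (mean Kyte-Doolittle hydropathy of the encoded protein), Aromo
#' (fraction of Phe/Tyr/Trp residues), L_aa (residue count, Met and Trp
#' included, terminal stop excluded) and L_sym (codons belonging to
#' degenerate families, i.e. L_aa minus Met and Trp counts).
#'
#' @param counts Named 64-codon count vector or genes x 64 matrix.
#' @return Tibble with columns `gravy`, `aromo`, `l_sym`, `l_aa`.
#' @export
protein_indices <- function(counts) {
  m <- as_count_matrix(counts)[, SENSE_CODONS, drop = FALSE]
  aa <- CODON_TO_AA[SENSE_CODONS]
  l_aa <- rowSums(m)
  kd <- as.vector(m %*% KYTE_DOOLITTLE[aa])
  arom <- rowSums(m[, aa %in% AROMATIC_AA, drop = FALSE])
  non_deg <- rowSums(m[, SENSE_CODONS %in% c("AUG", "UGG"), drop = FALSE])
  tibble::tibble(
    gravy = ifelse(l_aa > 0, kd / l_aa, NA_real_),
    aromo = ifelse(l_aa > 0, arom / l_aa, NA_real_),
    l_sym = as.integer(l_aa - non_deg),
    l_aa = as.integer(l_aa)
  )
}
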