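#' Wright's effective number of codons (ENC)
#'
#' For each amino acid with total usage n >= 2 and within-family usage
#' fractions p_i, the codon homozygosity is F = (n * sum(p_i^2) - 1) / (n - 1).
#' F is averaged within degeneracy classes of the standard code (9 two-fold,
#' 1 three-fold, 5 four-fold, 3 six-fold amino acids) and
#' ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6, capped at 61. An absent three-fold
#' class mean is imputed as (F2+F4)/2 and an absent six-fold mean as F4;
#' amino acids with n < 2, or with a non-positive F estimate, carry no
#' information and are excluded from the class means. A gene whose two-fold
#' or four-fold class mean is unavailable gets `NA`.
#'
#' @param counts Named 64-codon count vector or genes x 64 count matrix.
#' @return Numeric vector of ENC values in \[20, 61\] (one per gene).
#' @examples
#' enc(c(UUU = 3, UUC = 1, GCU = 2, GCA = 2))  # 46.4
#' @export
enc <- function(counts) {
  m <- as_count_matrix(counts)
  fam <- CODON_TO_AA[SENSE_CODONS]
  fam <- fam[!names(fam) %in% c("AUG", "UGG")]  # single-codon families excluded
  aas <- unique(fam)
  sizes <- family_sizes(fam)
  ng <- nrow(m)
  Fmat <- matrix(NA_real_, ng, length(aas), dimnames = list(NULL, aas))
  for (aa in aas) {
    cols <- names(fam)[fam == aa]
    x <- m[, cols, drop = FALSE]
    n <- rowSums(x)
    sum_p2 <- rowSums(x^2) / n^2
    f <- (n * sum_p2 - 1) / (n - 1)
    f[n < 2] <- NA_real_
    f[!is.na(f) & f <= 0] <- NA_real_
    Fmat[, aa] <- f
  }
  class_mean <- function(k) {
    cols <- names(sizes)[sizes == k]
    rowMeans(Fmat[, cols, drop = FALSE], na.rm = TRUE)
  }
  f2 <- class_mean(2); f3 <- class_mean(3)
  f4 <- class_mean(4); f6 <- class_mean(6)
  f3 <- ifelse(is.nan(f3), (f2 + f4) / 2, f3)
  f6 <- ifelse(is.nan(f6), f4, f6)
  out <- 2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6
  out[is.nan(f2) | is.nan(f4)] <- NA_real_
  pmin(out, 61)
}

#' Expected ENC under mutation alone
#'
#' The null ENC-plot curve: the ENC expected for a gene whose codon usage is
#' driven purely by the silent-site GC content s = GC3s,
#' ENC = 2 + s + 29 / (s^2 + (1 - s)^2). The curve peaks at 60.5 for
#' s = 0.5.
#'
#' @param gc3s Silent-site GC fraction(s) in \[0, 1\].
#' @return Expected ENC value(s).
#' @examples
#' expected_enc(c(0, 0.5, 1))  # 31, 60.5, 32
#' @export
expected_enc <- function(gc3s) {
  stopifnot(all(gc3s >= 0 & gc3s <= 1, na.rm = TRUE))
  2 + gc3s + 29 / (gc3s^2 + (1 - gc3s)^2)
}

#' ENC-ratio histogram
#'
#' Per gene, ratio = (ENC_expected - ENC_observed) / ENC_expected with the
#' expectation taken at the gene's GC3s; genes on the null curve give 0,
#' genes far below it give large positive ratios. Ratios are binned into
#' eight width-0.1 classes from -0.25 to 0.55; genes outside that range are
#' reported in an overflow row rather than dropped.
#'
#' @param enc_obs Observed per-gene ENC values.
#' @param gc3s Per-gene silent-site GC fractions.
#' @return Tibble with columns `class_limit`, `class_value`, `count`,
#'   `frequency_rate` (rates normalised over the in-range bins, as the
#'   published class tables are). The final row collects out-of-range or
#'   undefined genes (`class_value` `NA`).
#' @export
enc_ratio_histogram <- function(enc_obs, gc3s) {
  stopifnot(length(enc_obs) == length(gc3s))
  ratio <- (expected_enc(gc3s) - enc_obs) / expected_enc(gc3s)
  edges <- seq(-0.25, 0.55, by = 0.1)
  mids <- round(seq(-0.2, 0.5, by = 0.1), 10)
  bin <- cut(ratio, breaks = edges, right = FALSE)
  counts <- as.integer(table(bin))
  n_in <- sum(counts)
  out_of_range <- length(ratio) - n_in
  tibble::tibble(
    class_limit = c(paste(sprintf("%.2f", utils::head(edges, -1)),
                          sprintf("%.2f", edges[-1]), sep = "~"), "outside"),
    class_value = c(mids, NA_real_),
    count = c(counts, out_of_range),
    frequency_rate = c(if (n_in > 0) counts / n_in else rep(NA_real_, 8),
                       NA_real_)
  )
}
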