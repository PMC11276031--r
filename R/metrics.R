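#' Per-gene codon usage metrics table
#'
#' One row per gene with the full index set: ENC, positional GC (GC1, GC2,
#' GC3, GC12, GCall), silent-site composition (A3s/T3s/C3s/G3s, GC3s), CAI,
#' CBI, Fop, Gravy, Aromo, L_sym and L_aa.
#'
#' Defaults for the reference quantities follow the extreme-ENC convention:
#' CAI weights are built from the pooled counts of the `cai_ref_fraction`
#' of genes with the lowest ENC (the putative highly-expressed set) unless
#' `cai_weights` is supplied, and the optimal-codon set for CBI/Fop is the
#' delta-RSCU screen of [optimal_codons()] unless `optimal` is supplied
#' (falling back to the pooled high-frequency codons when the screen is
#' empty or the gene set is too small to split into expression groups).
#'
#' @param genes Gene tibble (`id`, `seq`).
#' @param scheme Family scheme for RSCU-derived quantities.
#' @param cai_weights Optional named CAI weight vector.
#' @param cai_ref_fraction Fraction of lowest-ENC genes defining the default
#'   CAI reference set.
#' @param optimal Optional character vector of optimal codons for CBI/Fop.
#' @param delta Delta-RSCU threshold for the default optimal-codon screen.
#' @return Tibble, one row per gene.
#' @export
metrics_table <- function(genes, scheme = c("split", "standard"),
                          cai_weights = NULL, cai_ref_fraction = 0.1,
                          optimal = NULL, delta = 0.08) {
  scheme <- match.arg(scheme)
  counts <- codon_count_matrix(genes)
  metrics_from_counts(counts, scheme = scheme, cai_weights = cai_weights,
                      cai_ref_fraction = cai_ref_fraction,
                      optimal = optimal, delta = delta)
}

#' @rdname metrics_table
#' @param counts Genes x 64 codon count matrix (rownames = gene ids).
#' @export
metrics_from_counts <- function(counts, scheme = c("split", "standard"),
                                cai_weights = NULL, cai_ref_fraction = 0.1,
                                optimal = NULL, delta = 0.08) {
  scheme <- match.arg(scheme)
  enc_val <- enc(counts)
  gc <- positional_gc(counts)
  sil <- silent_site_composition(counts)
  ids <- rownames(counts)

  if (is.null(cai_weights)) {
    ord <- order(enc_val, ids)
    n_ref <- max(1L, ceiling(cai_ref_fraction * nrow(counts)))
    ref <- pool_counts(counts[ord[seq_len(n_ref)], , drop = FALSE])
    cai_weights <- build_cai_weights(ref, scheme = scheme)
  }
  pooled <- pool_counts(counts)
  if (is.null(optimal)) {
    optimal <- tryCatch({
      grp <- expression_groups(tibble::tibble(id = ids, enc = enc_val))
      rep <- optimal_codons(
        pool_counts(counts[ids %in% grp$high, , drop = FALSE]),
        pool_counts(counts[ids %in% grp$low, , drop = FALSE]),
        rscu(pooled, scheme = scheme), threshold = delta, scheme = scheme)
      rep$codon[rep$optimal]
    }, error = function(e) character(0))
    if (length(optimal) == 0) {
      optimal <- high_frequency_codons(rscu(pooled, scheme = scheme))
    }
  }
  adap <- if (length(optimal)) cbi_fop(counts, optimal) else
    tibble::tibble(cbi = rep(NA_real_, nrow(counts)),
                   fop = rep(NA_real_, nrow(counts)))

  dplyr::bind_cols(
    tibble::tibble(id = ids,
                   n_codon = as.integer(rowSums(counts)),
                   enc = enc_val),
    gc, sil,
    tibble::tibble(cai = cai(counts, cai_weights)),
    adap,
    protein_indices(counts)
  )
}

#' Genome-level summary of a metrics table
#'
#' Arithmetic mean of every numeric per-gene index (the aggregation used for
#' genome-level index tables; pooled-count statistics such as genome RSCU
#' are computed from pooled counts instead).
#'
#' @param metrics Tibble from [metrics_table()].
#' @return One-row tibble of column means (NA values dropped).
#' @export
genome_summary <- function(metrics) {
  num <- dplyr::select(metrics, dplyr::where(is.numeric))
  dplyr::summarise(num, dplyr::across(dplyr::everything(),
                                      ~ mean(.x, na.rm = TRUE)))
}

#' Pairwise correlations among codon usage indices
#'
#' @param metrics Tibble from [metrics_table()] (>= 2 rows).
#' @param method `"pearson"` or `"spearman"`.
#' @return Symmetric correlation matrix with unit diagonal; `NA` for pairs
#'   involving a constant column.
#' @export
correlation_matrix <- function(metrics, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  num <- as.matrix(dplyr::select(metrics, dplyr::where(is.numeric)))
  stopifnot(nrow(num) >= 2)
  out <- suppressWarnings(stats::cor(num, use = "pairwise.complete.obs",
                                     method = method))
  diag(out) <- 1
  out
}

#' GC-content class labels
#'
#' Classifies genes into the three GC classes used to colour correspondence
#' analysis plots: low (< 45%), mid (45-60%) and high (>= 60%), with
#' left-closed boundaries.
#'
#' @param gc Numeric GC fractions in \[0, 1\].
#' @return Factor with levels `low`, `mid`, `high`.
#' @export
gc_class_labels <- function(gc) {
  stopifnot(all(gc >= 0 & gc <= 1, na.rm = TRUE))
  cut(gc, breaks = c(-Inf, 0.45, 0.60, Inf), labels = c("low", "mid", "high"),
      right = FALSE)
}
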