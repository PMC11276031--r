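#' Specification for a synthetic CDS set
#'
#' Describes a multi-gene CDS set with known statistical structure: gene
#' length distribution (uniform over in-frame lengths within
#' `length_range`, minimum 300 nt), amino-acid composition weights,
#' per-family codon preference (either a scalar bias `b` interpolating from
#' uniform usage at 0 to single-codon usage at 1, or explicit per-codon
#' preference weights), an optional target silent-position GC content
#' reached by tilting third-position base odds, and optional strata with
#' distinct preferences (an expression-linked bias gradient with a planted
#' truth for the delta-RSCU screen). Generated genes always satisfy the CDS
#' screening rules: they start with AUG, end with a stop codon, contain no
#' internal stop, and have in-frame length >= 300 nt.
#'
#' @param n_genes Number of genes.
#' @param length_range Gene length range in nucleotides, start and stop
#'   included; bounds are rounded to multiples of 3, minimum 300.
#' @param aa_weights Optional named weights over one-letter amino acid codes
#'   (defaults to uniform over the 20); normalised internally.
#' @param bias Scalar in \[0, 1\]: 0 = uniform synonymous usage, 1 = only the
#'   preferred codon of each family.
#' @param preferred Optional named character vector, family (amino acid) ->
#'   preferred codon; default is the alphabetically first codon of each
#'   family.
#' @param codon_prefs Optional named non-negative weights over sense codons,
#'   overriding `bias`/`preferred` for the families they cover; normalised
#'   within each family.
#' @param gc3_target Optional target third-position GC fraction of body
#'   codons; achieved by exponential tilting of each family's preference
#'   toward/away from G/C-ending codons. An unreachable target (e.g. 1 with
#'   AT-only preferences) is an error.
#' @param strata Optional list of strata, each a list with a `fraction`
#'   field plus any of `bias`, `preferred`, `codon_prefs`, `gc3_target`,
#'   `label` overriding the top-level values; fractions must sum to 1.
#'   Genes are assigned to strata in contiguous id blocks.
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return A list of class `"genome_spec"`.
#' @export
genome_spec <- function(n_genes, length_range = c(300, 1800),
                        aa_weights = NULL, bias = 0, preferred = NULL,
                        codon_prefs = NULL, gc3_target = NULL,
                        strata = NULL, seed = 1L) {
  stopifnot(n_genes >= 1, length(length_range) == 2,
            length_range[1] >= 300, length_range[2] >= length_range[1],
            bias >= 0, bias <= 1)
  if (!is.null(gc3_target)) stopifnot(gc3_target > 0, gc3_target < 1)
  if (!is.null(strata)) {
    fr <- vapply(strata, function(s) s$fraction, numeric(1))
    stopifnot(abs(sum(fr) - 1) < 1e-8, all(fr > 0))
  }
  out <- list(n_genes = as.integer(n_genes), length_range = length_range,
              aa_weights = aa_weights, bias = bias, preferred = preferred,
              codon_prefs = codon_prefs, gc3_target = gc3_target,
              strata = strata, seed = as.integer(seed))
  class(out) <- "genome_spec"
  out
}

# within-family preference vector over the 61 sense codons (standard
# amino-acid families), normalised to sum 1 per family
build_prefs <- function(bias = 0, preferred = NULL, codon_prefs = NULL) {
  fam <- CODON_TO_AA[SENSE_CODONS]
  pref <- stats::setNames(numeric(length(SENSE_CODONS)), SENSE_CODONS)
  for (aa in unique(fam)) {
    cods <- sort(names(fam)[fam == aa])
    k <- length(cods)
    if (!is.null(codon_prefs) && any(cods %in% names(codon_prefs))) {
      v <- stats::setNames(numeric(k), cods)
      v[intersect(cods, names(codon_prefs))] <-
        codon_prefs[intersect(cods, names(codon_prefs))]
      if (any(v < 0) || sum(v) == 0) stop("invalid codon preferences for ", aa)
      pref[cods] <- v / sum(v)
    } else {
      top <- if (!is.null(preferred) && aa %in% names(preferred)) {
        stopifnot(preferred[[aa]] %in% cods)
        preferred[[aa]]
      } else cods[1]
      v <- rep((1 - bias) / k, k)
      names(v) <- cods
      v[top] <- v[top] + bias
      pref[cods] <- v
    }
  }
  pref
}

# tilt per-family preferences so expected third-position GC of body codons
# equals `target`; returns the tilted preference vector
tilt_gc3 <- function(pref, aa_weights, target) {
  fam <- CODON_TO_AA[SENSE_CODONS]
  gc3 <- as.numeric(is_gc_base(third_base(SENSE_CODONS)))
  w_aa <- aa_weights[fam]
  expected <- function(log_t) {
    p <- pref * exp(log_t * gc3)
    tot <- stats::ave(p, fam, FUN = sum)
    sum(w_aa * p / tot * gc3)
  }
  lo <- expected(-40); hi <- expected(40)
  if (target <= lo || target >= hi) {
    stop("gc3_target ", target, " is unreachable (achievable range ",
         signif(lo, 3), "-", signif(hi, 3), ")")
  }
  root <- stats::uniroot(function(z) expected(z) - target, c(-40, 40),
                         tol = 1e-12)$root
  p <- pref * exp(root * gc3)
  tot <- stats::ave(p, fam, FUN = sum)
  p / tot * stats::ave(pref, fam, FUN = sum)
}

#' Generate a synthetic CDS set
#'
#' Draws each gene as AUG + independently sampled sense codons + one stop
#' codon (uniform over UAA/UAG/UGA). Body codons are sampled from the
#' distribution implied by the spec's amino-acid weights and within-family
#' preferences (site-independent, no codon-pair structure). The returned
#' truth record stores the exact generating distributions and stratum
#' labels, so planted structure can be checked downstream.
#'
#' @param spec A [genome_spec()].
#' @return List with `genes` (tibble: id, seq, length_nt) and `truth` (list:
#'   `strata` tibble of id, stratum label; `prefs` per-stratum normalised
#'   within-family preferences; `codon_dist` per-stratum body codon
#'   distribution over the 61 sense codons; `seed`).
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  set.seed(spec$seed)
  aa_w <- spec$aa_weights
  if (is.null(aa_w)) {
    aa20 <- sort(unique(unname(CODON_TO_AA[SENSE_CODONS])))
    aa_w <- stats::setNames(rep(1, length(aa20)), aa20)
  }
  aa_w <- aa_w / sum(aa_w)

  strata <- spec$strata
  if (is.null(strata)) strata <- list(list(fraction = 1))
  n_per <- diff(round(cumsum(c(0, vapply(strata, `[[`, numeric(1), "fraction"))) *
                        spec$n_genes))
  n_per[length(n_per)] <- spec$n_genes - sum(n_per[-length(n_per)])

  min_cod <- ceiling(spec$length_range[1] / 3)
  max_cod <- floor(spec$length_range[2] / 3)
  fam <- CODON_TO_AA[SENSE_CODONS]

  ids <- sprintf("g%05d", seq_len(spec$n_genes))
  seqs <- character(spec$n_genes)
  labels <- character(spec$n_genes)
  truth_prefs <- list()
  truth_dist <- list()
  offset <- 0L

  for (si in seq_along(strata)) {
    st <- strata[[si]]
    label <- st$label %||% paste0("stratum", si)
    pref <- build_prefs(
      bias = st$bias %||% spec$bias,
      preferred = st$preferred %||% spec$preferred,
      codon_prefs = st$codon_prefs %||% spec$codon_prefs
    )
    gc3t <- st$gc3_target %||% spec$gc3_target
    if (!is.null(gc3t)) pref <- tilt_gc3(pref, aa_w, gc3t)
    q <- aa_w[fam] * pref
    q <- q / sum(q)

    ng <- n_per[si]
    if (ng == 0) next
    n_cod <- if (min_cod == max_cod) rep(min_cod, ng) else
      sample(seq(min_cod, max_cod), ng, replace = TRUE)
    body_len <- n_cod - 2L
    body <- sample(SENSE_CODONS, sum(body_len), replace = TRUE, prob = q)
    gene_of <- rep(seq_len(ng), times = body_len)
    stops <- sample(STOP_CODONS, ng, replace = TRUE)
    bodies <- vapply(split(body, gene_of), paste, character(1), collapse = "")
    idx <- offset + seq_len(ng)
    seqs[idx] <- paste0(START_CODON, bodies, stops)
    labels[idx] <- label
    truth_prefs[[label]] <- pref
    truth_dist[[label]] <- q
    offset <- offset + ng
  }

  list(
    genes = tibble::tibble(id = ids, seq = seqs, length_nt = nchar(seqs)),
    truth = list(
      strata = tibble::tibble(id = ids, stratum = labels),
      prefs = truth_prefs,
      codon_dist = truth_dist,
      aa_weights = aa_w,
      seed = spec$seed
    )
  )
}

#' Generate a genome under a pure mutational GC gradient
#'
#' Each gene draws its body codons from the base-composition distribution
#' of a mutation-only model: at every codon position the base is G or C
#' with probability m/2 each and A or U with probability (1-m)/2 each,
#' restricted to sense codons and renormalised. The mutational GC parameter
#' m varies across genes on an even grid over `gc_range`, so codon usage
#' varies purely through mutation pressure with no selective preference
#' among synonymous codons. The truth record carries, per gene, m and the
#' exact expected positional GC fractions (start codon included, as the
#' observed metrics count it), from which the generating neutrality slope
#' can be computed.
#'
#' @param n_genes Number of genes.
#' @param gc_range Range of the mutational GC parameter.
#' @param length_range Gene length range in nucleotides.
#' @param seed Integer seed.
#' @return List with `genes` and `truth` (tibble: id, m, e_gc1, e_gc2,
#'   e_gc3, e_gc12).
#' @export
generate_mutation_genome <- function(n_genes = 500, gc_range = c(0.25, 0.75),
                                     length_range = c(1800, 4500), seed = 1L) {
  stopifnot(n_genes >= 2, gc_range[1] > 0, gc_range[2] < 1,
            length_range[1] >= 300)
  set.seed(seed)
  m_grid <- seq(gc_range[1], gc_range[2], length.out = n_genes)
  min_cod <- ceiling(length_range[1] / 3)
  max_cod <- floor(length_range[2] / 3)
  n_cod <- if (min_cod == max_cod) rep(min_cod, n_genes) else
    sample(seq(min_cod, max_cod), n_genes, replace = TRUE)

  base_mat <- vapply(1:3, function(k) substr(SENSE_CODONS, k, k), character(61))
  gc_mat <- matrix(is_gc_base(base_mat), ncol = 3)

  ids <- sprintf("g%05d", seq_len(n_genes))
  seqs <- character(n_genes)
  e_gc <- matrix(NA_real_, n_genes, 3)
  aug_gc <- is_gc_base(c("A", "U", "G"))
  for (i in seq_len(n_genes)) {
    m <- m_grid[i]
    base_p <- ifelse(gc_mat, m / 2, (1 - m) / 2)
    q <- base_p[, 1] * base_p[, 2] * base_p[, 3]
    q <- q / sum(q)
    body_n <- n_cod[i] - 2L
    body <- sample(SENSE_CODONS, body_n, replace = TRUE, prob = q)
    stop_cod <- sample(STOP_CODONS, 1)
    seqs[i] <- paste0(START_CODON, paste(body, collapse = ""), stop_cod)
    # expectation over the sense codons positional_gc() sees: body + AUG
    e_body <- colSums(q * gc_mat)
    e_gc[i, ] <- (body_n * e_body + aug_gc) / (body_n + 1)
  }
  list(
    genes = tibble::tibble(id = ids, seq = seqs, length_nt = nchar(seqs)),
    truth = tibble::tibble(id = ids, m = m_grid,
                           e_gc1 = e_gc[, 1], e_gc2 = e_gc[, 2],
                           e_gc3 = e_gc[, 3],
                           e_gc12 = (e_gc[, 1] + e_gc[, 2]) / 2)
  )
}

#' FASTA fixture with one violation of each CDS screening rule
#'
#' Deterministically emits seven DNA-alphabet records: one valid control and
#' one sequence violating each screening rule (frameshifted length, short,
#' ambiguous base, wrong start codon, missing stop, internal stop), so a
#' filter run yields exactly 1 kept and 6 rejected records with 6 distinct
#' reason codes.
#'
#' @return Character scalar of FASTA text (byte-identical across calls).
#' @export
fixture_invalid_cds <- function() {
  body98 <- paste(rep(c("GCT", "AAA", "GAT", "TGC", "GAA", "TTT", "GGT"),
                      length.out = 98), collapse = "")
  valid <- paste0("ATG", body98, "TAA")                      # 300 nt, clean
  frameshift <- substr(valid, 1, 299)                        # not a multiple of 3
  short <- paste0("ATG", substr(body98, 1, 84), "TAA")       # 90 nt < 300
  ambiguous <- paste0(substr(valid, 1, 9), "N", substr(valid, 11, 300))
  bad_start <- paste0("GCC", substr(valid, 4, 300))
  no_stop <- paste0(substr(valid, 1, 297), "GCA")
  internal <- paste0(substr(valid, 1, 150), "TGA", substr(valid, 154, 300))
  recs <- c(valid = valid, frameshift = frameshift, short = short,
            ambiguous = ambiguous, bad_start = bad_start,
            no_stop = no_stop, internal_stop = internal)
  paste0(paste0(">", names(recs), "\n", recs, collapse = "\n"), "\n")
}
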