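# shared helpers for building in-code fixtures

RNA_CODONS_T <- cubkit:::RNA_CODONS
SENSE_T <- cubkit:::SENSE_CODONS
SYN_T <- cubkit:::SYN_CODONS
STOPS_T <- cubkit:::STOP_CODONS
COD2AA_T <- cubkit:::CODON_TO_AA

# assemble an in-frame CDS from body codons
make_cds <- function(body, stop = "UAA") {
  paste0("AUG", paste(body, collapse = ""), stop)
}

# random 64-codon count vector, reproducible
rand_counts <- function(seed, lambda = 40) {
  set.seed(seed)
  stats::setNames(stats::rpois(64, lambda), RNA_CODONS_T)
}

# deterministic count vector with bias b toward the alphabetically first
# codon of each standard family, `scale` counts per family
biased_counts <- function(b, scale = 1200) {
  fam <- COD2AA_T[SENSE_T]
  counts <- stats::setNames(numeric(64), RNA_CODONS_T)
  for (aa in unique(fam)) {
    cods <- sort(names(fam)[fam == aa])
    k <- length(cods)
    v <- rep((1 - b) / k, k)
    v[1] <- v[1] + b
    counts[cods] <- round(v * scale)
  }
  counts
}

# gene tibble from a character vector of sequences
gene_tbl <- function(seqs, ids = sprintf("g%03d", seq_along(seqs))) {
  tibble::tibble(id = ids, seq = seqs, length_nt = nchar(seqs))
}

published_split_rscu <- function(species) {
  cnt <- cubkit::published_codon_counts()
  r <- cubkit::rscu(stats::setNames(cnt[[species]], cnt$codon), scheme = "split")
  r
}
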