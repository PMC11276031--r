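test_that("codon counting is exact, linear and conserved under pooling", {
  x <- count_codons("AUGAAAUAA")
  expect_equal(sum(x), 3L)
  expect_equal(unname(x[c("AUG", "AAA", "UAA")]), c(1L, 1L, 1L))
  expect_error(count_codons("AUGA"), "multiple")

  genes <- generate_genome(genome_spec(3, c(300, 600), seed = 2))$genes
  m <- codon_count_matrix(genes)
  expect_equal(dim(m), c(3L, 64L))
  expect_equal(unname(rowSums(m)), genes$length_nt / 3)
  # pooling two copies of a gene doubles every count
  expect_equal(pool_counts(m[c(1, 1), ]), stats::setNames(2L * m[1, ], colnames(m)))
  # pooled counts equal the sum of the per-gene tables
  expect_equal(pool_counts(m), m[1, ] + m[2, ] + m[3, ])
})

test_that("RSCU reproduces published values under the split scheme", {
  ala <- c(GCA = 328432, GCC = 173863, GCG = 91978, GCU = 301610)
  expect_equal(round(rscu(ala)$rscu[1], 3), 1.466)

  leu <- c(CUA = 114756, CUC = 168150, CUG = 182510, CUU = 279707,
           UUA = 123649, UUG = 269356)
  split <- rscu(leu, scheme = "split")
  expect_equal(round(split$rscu[split$codon == "CUU"], 3), 1.502)
  expect_equal(round(split$rscu[split$codon == "UUG"], 3), 1.371)
  std <- rscu(leu, scheme = "standard")
  expect_equal(std$rscu[std$codon == "CUU"], 1.4746, tolerance = 5e-4)
})

test_that("RSCU normalisation, missing families and scheme invariants hold", {
  # equal counts in a family -> all RSCU 1
  eq <- rscu(c(GGA = 7, GGC = 7, GGG = 7, GGU = 7))
  expect_equal(eq$rscu[eq$amino_acid == "G"], rep(1, 4))

  for (seed in 1:5) {
    counts <- rand_counts(seed)
    for (scheme in c("split", "standard")) {
      r <- rscu(counts, scheme = scheme)
      sums <- as.vector(tapply(r$rscu, r$family, sum))
      sizes <- as.vector(tapply(r$rscu, r$family, length))
      expect_equal(unname(sums), unname(as.numeric(sizes)), tolerance = 1e-12)
    }
  }
  # family with zero total -> NA, not zero
  z <- rand_counts(9)
  z[c("GGA", "GGC", "GGG", "GGU")] <- 0
  expect_true(all(is.na(rscu(z)$rscu[rscu(z)$amino_acid == "G"])))
  # single-codon families are identically 1
  r <- rscu(rand_counts(3))
  expect_equal(r$rscu[r$codon %in% c("AUG", "UGG")], c(1, 1))
})

test_that("pooled RSCU is the RSCU of pooled counts, not the mean of genes", {
  genes <- generate_genome(genome_spec(12, c(300, 900), bias = 0.4, seed = 8))$genes
  m <- codon_count_matrix(genes)
  pooled_r <- rscu(pool_counts(m))
  mean_of_gene_r <- colMeans(rscu_matrix(m), na.rm = TRUE)
  direct <- rscu_matrix(matrix(pool_counts(m), nrow = 1,
                               dimnames = list("p", colnames(m))))[1, ]
  expect_equal(pooled_r$rscu[match(names(direct), pooled_r$codon)],
               unname(direct))
  expect_gt(max(abs(mean_of_gene_r -
                      direct[names(mean_of_gene_r)]), na.rm = TRUE), 1e-6)
})

test_that("positional GC handles pure-composition cases and its identities", {
  g <- positional_gc(c(GGG = 50))
  expect_equal(unlist(g), c(gc1 = 1, gc2 = 1, gc3 = 1, gc12 = 1, gc_all = 1))
  alt <- positional_gc(count_codons(paste(rep("AUAUAU", 20), collapse = "")))
  expect_equal(alt$gc1 + alt$gc2 + alt$gc3, 0)

  for (seed in 1:5) {
    g <- positional_gc(rand_counts(seed))
    expect_equal(g$gc12, (g$gc1 + g$gc2) / 2, tolerance = 1e-12)
    expect_equal(g$gc_all, (g$gc1 + g$gc2 + g$gc3) / 3, tolerance = 1e-12)
  }
  # stop codons are excluded: adding stops changes nothing
  x <- rand_counts(4)
  y <- x; y[STOPS_T] <- y[STOPS_T] + 100
  expect_equal(positional_gc(x), positional_gc(y))
  expect_error(positional_gc(stats::setNames(integer(64), RNA_CODONS_T)),
               "sense")
})

test_that("silent-site composition follows the possible-base convention", {
  one <- silent_site_composition(c(GCG = 30))
  expect_equal(one$g3s, 1)
  expect_equal(one$gc3s, 1)
  expect_equal(one$a3s, 0)

  # equal counts of every synonymous codon: oracle by enumeration over the
  # code table
  eq <- stats::setNames(rep(10, length(SYN_T)), SYN_T)
  got <- silent_site_composition(eq)
  third <- substr(SYN_T, 3, 3)
  expect_equal(got$gc3s, mean(third %in% c("G", "C")))
  fam <- COD2AA_T[SYN_T]
  oracle_frac <- function(base) {
    fams_with <- unique(fam[third == base])
    sum(third == base) / sum(fam %in% fams_with)
  }
  expect_equal(got$a3s, oracle_frac("A"))
  expect_equal(got$t3s, oracle_frac("U"))
  expect_equal(got$c3s, oracle_frac("C"))
  expect_equal(got$g3s, oracle_frac("G"))

  # general counts: fractions need not sum to 1 ...
  r <- silent_site_composition(rand_counts(6))
  expect_false(isTRUE(all.equal(r$a3s + r$t3s + r$c3s + r$g3s, 1)))
  # ... but on a genome of four-fold families only, they do
  four <- c(GCA = 3, GCC = 9, GCG = 1, GCU = 2, GGA = 5, GGC = 1, GGG = 2,
            GGU = 8, CCA = 4, CCC = 2, CCG = 6, CCU = 1)
  f <- silent_site_composition(four)
  expect_equal(f$a3s + f$t3s + f$c3s + f$g3s, 1, tolerance = 1e-12)
})

test_that("ENC hits Wright's limits, the worked value, and responds to bias", {
  uniform <- stats::setNames(rep(50, length(SENSE_T)), SENSE_T)
  expect_equal(enc(uniform), 61)
  one_per_aa <- biased_counts(1)
  expect_equal(enc(one_per_aa), 20)
  expect_equal(enc(c(UUU = 3, UUC = 1, GCU = 2, GCA = 2)), 46.4)
  expect_true(is.na(enc(c(AAA = 5))))

  # monotone: stronger within-family bias never increases ENC
  vals <- vapply(seq(0, 1, by = 0.2), function(b) enc(biased_counts(b)),
                 numeric(1))
  expect_true(all(diff(vals) <= 1e-9))
  expect_true(all(vals >= 20 & vals <= 61))
})

test_that("CAI weights and geometric mean follow the reference definition", {
  ref <- biased_counts(0.5)
  w <- build_cai_weights(ref, scheme = "split")
  fam <- codon_families("split")[SYN_T]
  expect_equal(as.vector(tapply(w, fam, max)), rep(1, length(unique(fam))))

  # gene using only family-maximal codons -> CAI 1
  top <- names(w)[w == 1]
  gene_top <- stats::setNames(rep(5, length(top)), top)
  expect_equal(cai(gene_top, w), 1)

  # two-codon gene with weights 0.25 and 1 -> sqrt(0.25) = 0.5
  expect_equal(cai(c(GGU = 1, GGA = 1), c(GGU = 0.25, GGA = 1)), 0.5)

  # log-domain brute force on a 100-codon gene
  set.seed(31)
  body <- sample(SYN_T, 100, replace = TRUE)
  counts <- count_codons(make_cds(body))
  expect_equal(cai(counts, w), exp(mean(log(w[body]))))

  # zero-count codons in the reference get the 0.01 floor
  ref0 <- ref; ref0["GGG"] <- 0
  expect_equal(unname(build_cai_weights(ref0)["GGG"]), 0.01)
})

test_that("CBI and Fop behave at their fixed points", {
  fam <- COD2AA_T[SYN_T]
  optimal <- vapply(split(SYN_T, fam), `[`, character(1), 1)
  only_opt <- stats::setNames(rep(4, length(optimal)), optimal)
  r <- cbi_fop(only_opt, unname(optimal))
  expect_equal(r$fop, 1)
  expect_equal(r$cbi, 1)

  no_opt <- stats::setNames(rep(4, length(SYN_T)), SYN_T)
  no_opt[optimal] <- 0
  expect_equal(cbi_fop(no_opt, unname(optimal))$fop, 0)

  uniform <- stats::setNames(rep(6, length(SYN_T)), SYN_T)
  expect_equal(cbi_fop(uniform, unname(optimal))$cbi, 0, tolerance = 1e-12)
})

test_that("protein indices match the hydropathy and aromaticity tables", {
  expect_equal(protein_indices(c(GCU = 25))$gravy, 1.8)
  fyw <- protein_indices(c(UUU = 3, UAC = 2, UGG = 5))
  expect_equal(fyw$aromo, 1)
  expect_equal(fyw$l_aa, 10L)
  expect_equal(fyw$l_sym, 5L)  # Trp is non-degenerate

  # mixed 10-residue protein against a hand-summed hydropathy table
  body <- c("AUG", "GCU", "CGU", "AAU", "GAU", "UGU", "CAA", "GAA", "GGU", "CAU")
  kd <- c(M = 1.9, A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
          Q = -3.5, E = -3.5, G = -0.4, H = -3.2)
  got <- protein_indices(count_codons(paste(c(body, "UAA"), collapse = "")))
  expect_equal(got$gravy, mean(kd))
  expect_equal(got$l_aa, 10L)
  expect_equal(got$l_sym, 9L)
})

test_that("metrics table aggregates and correlates coherently", {
  genes <- generate_genome(genome_spec(40, c(300, 900), bias = 0.2, seed = 13))$genes
  met <- metrics_table(genes)
  expect_equal(nrow(met), 40L)
  expect_true(all(met$enc >= 20 & met$enc <= 61))
  frac_cols <- c("gc1", "gc2", "gc3", "gc12", "gc_all", "gc3s", "fop", "aromo")
  for (cc in frac_cols) expect_true(all(met[[cc]] >= 0 & met[[cc]] <= 1))
  expect_equal(genome_summary(met)$gc_all, mean(met$gc_all))

  cm <- correlation_matrix(met)
  expect_equal(cm, t(cm))
  expect_equal(unname(diag(cm)), rep(1, ncol(cm)))
  expect_equal(cm["gc12", "gc_all"], stats::cor(met$gc12, met$gc_all))

  # two identical genes: zero variance, correlations undefined
  twin <- gene_tbl(rep(genes$seq[1], 2))
  cm2 <- correlation_matrix(metrics_table(twin, optimal = "GCU",
                                          cai_weights = build_cai_weights(biased_counts(0.3))))
  off <- cm2[upper.tri(cm2)]
  expect_true(all(is.na(off)))
})
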