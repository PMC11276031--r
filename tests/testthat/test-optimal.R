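test_that("high-frequency codon sets from published pooled counts", {
  cnt <- published_codon_counts()
  hf <- lapply(c(ac = "ac", cr = "cr", dc = "dc", sm = "sm"), function(sp) {
    high_frequency_codons(rscu(stats::setNames(cnt[[sp]], cnt$codon)))
  })
  expect_equal(lengths(hf), c(ac = 28L, cr = 28L, dc = 29L, sm = 31L))
  expect_true(all(c("GCA", "CUU") %in% hf$ac))
  # uniform usage -> empty set
  uniform <- stats::setNames(rep(9, length(SENSE_T)), SENSE_T)
  expect_length(high_frequency_codons(rscu(uniform)), 0)
})

test_that("expression groups are disjoint, sized and deterministic", {
  met <- tibble::tibble(id = sprintf("g%03d", 1:100), enc = seq(25, 60, length.out = 100))
  grp <- expression_groups(met)
  expect_length(grp$high, 10)
  expect_length(grp$low, 10)
  expect_length(intersect(grp$high, grp$low), 0)
  # default direction: lowest ENC = high expression
  expect_setequal(grp$high, met$id[1:10])
  lit <- expression_groups(met, direction = "literal")
  expect_setequal(lit$high, met$id[91:100])

  ties <- tibble::tibble(id = sprintf("g%03d", 1:20), enc = rep(50, 20))
  expect_warning(grp2 <- expression_groups(ties), "equal")
  expect_equal(grp2$high, sprintf("g%03d", 1:2))
  expect_length(intersect(grp2$high, grp2$low), 0)

  expect_error(expression_groups(met[1:5, ], fraction = 0.5), "too few")
})

test_that("a planted low-ENC subpopulation lands in the high-expression group", {
  spec <- genome_spec(100, c(900, 1200), seed = 43, strata = list(
    list(fraction = 0.9, bias = 0, label = "background"),
    list(fraction = 0.1, bias = 0.9, label = "planted")))
  sim <- generate_genome(spec)
  met <- metrics_table(sim$genes, optimal = "GCU")
  grp <- expression_groups(met)
  planted <- sim$truth$strata$id[sim$truth$strata$stratum == "planted"]
  expect_setequal(grp$high, planted)
})

test_that("the delta-RSCU screen applies all three conditions inclusively", {
  uniform <- stats::setNames(rep(50, length(SENSE_T)), SENSE_T)
  pooled <- rscu(uniform)
  same <- optimal_codons(uniform, uniform, pooled)
  expect_equal(same$delta_rscu, rep(0, nrow(same)))
  expect_false(any(same$optimal))

  # engineered boundary: Lys delta exactly 0.08, all conditions met
  high <- uniform; high["AAA"] <- 46; high["AAG"] <- 54
  low <- uniform; low["AAA"] <- 50; low["AAG"] <- 50
  pooled_counts <- uniform; pooled_counts["AAA"] <- 96; pooled_counts["AAG"] <- 104
  rep <- optimal_codons(high, low, rscu(pooled_counts))
  aag <- rep[rep$codon == "AAG", ]
  expect_equal(aag$delta_rscu, 0.08)
  expect_true(aag$optimal)
  # same contrast but pooled RSCU at 1 fails the high-frequency condition
  rep2 <- optimal_codons(high, low, rscu(uniform))
  expect_false(rep2$optimal[rep2$codon == "AAG"])
})

test_that("shared codon sets intersect with ending tallies", {
  cnt <- published_codon_counts()
  hf <- lapply(c(ac = "ac", cr = "cr", dc = "dc", sm = "sm"), function(sp) {
    high_frequency_codons(rscu(stats::setNames(cnt[[sp]], cnt$codon)))
  })
  four <- shared_codons(hf)
  expect_length(four$shared, 9)
  three <- shared_codons(hf[c("ac", "cr", "dc")])
  expect_length(three$shared, 24)
  tb <- substr(three$shared, 3, 3)
  expect_equal(sum(tb %in% c("A", "U")) / length(three$shared), 0.875)
  sm_row <- shared_codons(hf)$endings
  expect_equal(sm_row$n_cg_ending[sm_row$set == "sm"], 25L)

  expect_length(shared_codons(list(c("GCU"), c("AAA")))$shared, 0)
  # commutative and associative
  expect_equal(shared_codons(hf[c(4, 2, 3, 1)])$shared, four$shared)
  nested <- shared_codons(list(shared_codons(hf[1:2])$shared,
                               shared_codons(hf[3:4])$shared))$shared
  expect_equal(nested, four$shared)
})

test_that("the optimal set is invariant under gene reordering", {
  sim <- generate_genome(genome_spec(60, c(600, 900), bias = 0.3, seed = 47))
  run_screen <- function(genes) {
    m <- codon_count_matrix(genes)
    met <- metrics_from_counts(m, optimal = "GCU")
    grp <- expression_groups(met)
    rep <- optimal_codons(
      pool_counts(m[rownames(m) %in% grp$high, , drop = FALSE]),
      pool_counts(m[rownames(m) %in% grp$low, , drop = FALSE]),
      rscu(pool_counts(m)))
    rep$codon[rep$optimal]
  }
  shuffled <- sim$genes[rev(seq_len(nrow(sim$genes))), ]
  expect_equal(run_screen(sim$genes), run_screen(shuffled))
})
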