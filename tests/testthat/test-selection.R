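test_that("the expected-ENC curve matches its closed form", {
  expect_equal(expected_enc(0.5), 60.5)
  expect_equal(expected_enc(0), 31)
  expect_equal(expected_enc(1), 32)
  s <- seq(0.05, 0.95, by = 0.05)
  expect_equal(expected_enc(s), 2 + s + 29 / (s^2 + (1 - s)^2))
  # the rational term is symmetric about 0.5; the curve itself is not, and
  # its true maximum sits a hair above expected_enc(0.5) = 60.5
  expect_equal(expected_enc(0.3) - 0.3, expected_enc(0.7) - 0.7)
  expect_equal(max(expected_enc(seq(0, 1, by = 0.001))), 60.5, tolerance = 1e-4)
  expect_gte(max(expected_enc(seq(0, 1, by = 0.001))), 60.5)
})

test_that("ENC-ratio histogram bins genes and conserves counts", {
  gc3s <- c(0.5, 0.5, 0.5, 0.2)
  obs <- c(expected_enc(0.5),          # on the curve -> class 0
           expected_enc(0.5) / 2,      # ratio 0.5 -> class 0.5
           expected_enc(0.5) * 1.3,    # ratio -0.3 -> outside
           expected_enc(0.2) * 0.88)   # ratio 0.12 -> class 0.1
  h <- enc_ratio_histogram(obs, gc3s)
  expect_equal(nrow(h), 9L)
  expect_equal(h$count[h$class_value %in% 0], 1L)
  expect_equal(h$count[h$class_value %in% 0.5], 1L)
  expect_equal(h$count[h$class_value %in% 0.1], 1L)
  expect_equal(h$count[is.na(h$class_value)], 1L)
  expect_equal(sum(h$frequency_rate, na.rm = TRUE), 1)
  expect_equal(sum(h$count), 4L)
})

test_that("an unbiased genome sits tightly around the null ENC curve", {
  genes <- generate_genome(genome_spec(200, c(1500, 1500), seed = 17))$genes
  met <- metrics_table(genes, optimal = "GCU")
  h <- enc_ratio_histogram(met$enc, met$gc3s)
  central <- h$frequency_rate[!is.na(h$class_value) & h$class_value == 0]
  expect_gte(central, 0.95)
})

test_that("PR2 coordinates read third-position balance", {
  parity <- c(GCA = 5, GCU = 5, GCG = 5, GCC = 5)
  expect_equal(unlist(pr2_point(parity)), c(x = 0.5, y = 0.5))
  expect_equal(pr2_point(c(GGG = 10, CAG = 5))$x, 1)
  # third-position tallies A=2, T=6, G=6, C=2 -> lower-right quadrant
  toy <- c(GCA = 2, GCU = 6, GCG = 6, GCC = 2)
  p <- pr2_point(toy)
  expect_equal(unlist(p), c(x = 0.75, y = 0.25))
  expect_true(p$x > 0.5 && p$y < 0.5)
  # AUG and UGG are excluded from the default site set
  expect_equal(pr2_point(c(parity, AUG = 50, UGG = 50)),
               pr2_point(parity))
  # zero denominator -> missing
  expect_true(is.na(pr2_point(c(GCA = 3, GCU = 3))$x))
})

test_that("neutrality regression recovers exact fixed points", {
  gc3 <- seq(0.2, 0.8, length.out = 20)
  ident <- neutrality_fit(gc3, gc3)
  expect_equal(ident$slope, 1, tolerance = 1e-12)
  expect_equal(ident$pearson_r, 1, tolerance = 1e-12)
  expect_equal(ident$mutation_share, 100)

  flat <- neutrality_fit(rep(0.45, 20), gc3)
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_equal(flat$selection_share, 100)

  tilted <- neutrality_fit(0.3 + 0.146 * gc3, gc3)
  expect_equal(tilted$mutation_share, 14.6, tolerance = 1e-9)
  expect_false(tilted$slope_negative)

  neg <- neutrality_fit(0.5 - 0.044 * gc3, gc3)
  expect_true(neg$slope_negative)
  expect_equal(neg$mutation_share, 4.4, tolerance = 1e-9)
  expect_equal(neg$mutation_share + neg$selection_share, 100)

  expect_error(neutrality_fit(gc3, rep(0.5, 20)), "variance")
})

test_that("neutrality slope is recovered on mutation-driven genomes", {
  sim <- generate_mutation_genome(n_genes = 500, seed = 23)
  met <- positional_gc(codon_count_matrix(sim$genes))
  fit <- neutrality_fit(met$gc12, met$gc3)
  oracle <- stats::coef(stats::lm(e_gc12 ~ e_gc3, data = sim$truth))[2]
  expect_equal(fit$slope, unname(oracle), tolerance = 0.05)
  expect_gt(fit$pearson_r, 0.9)

  # third-position-only pressure: GC12 flat, generating slope 0
  spec3 <- genome_spec(300, c(1500, 3000), gc3_target = 0.3, seed = 29,
                       strata = list(
                         list(fraction = 0.5, gc3_target = 0.3),
                         list(fraction = 0.5, gc3_target = 0.7)))
  g3 <- generate_genome(spec3)
  met3 <- positional_gc(codon_count_matrix(g3$genes))
  fit3 <- neutrality_fit(met3$gc12, met3$gc3)
  expect_equal(fit3$slope, 0, tolerance = 0.05)
})

test_that("PR2 points centre on the parity point without selection", {
  genes <- generate_genome(genome_spec(500, c(900, 1500), seed = 37))$genes
  p <- pr2_point(codon_count_matrix(genes))
  # uniform synonymous usage is strand-symmetric only family by family;
  # the genome-wide centre is the code-table average, computed exactly
  fam <- COD2AA_T[SYN_T]
  third <- substr(SYN_T, 3, 3)
  w <- 1 / as.numeric(table(fam)[fam]) / length(unique(COD2AA_T[SENSE_T]))
  ex <- function(b) sum(w[third == b])
  expect_equal(mean(p$x), ex("G") / (ex("G") + ex("C")), tolerance = 0.02)
  expect_equal(mean(p$y), ex("A") / (ex("A") + ex("U")), tolerance = 0.02)
})

test_that("correspondence analysis matches a dense eigen oracle", {
  x <- matrix(c(10, 2, 4,
                3, 9, 5,
                6, 7, 1,
                2, 2, 8), nrow = 4, byrow = TRUE)
  res <- correspondence_analysis(x)
  # oracle: eigendecomposition of S'S with S the standardized residuals
  p <- x / sum(x); r <- rowSums(p); c <- colSums(p)
  s <- (p - outer(r, c)) / sqrt(outer(r, c))
  ev <- sort(eigen(t(s) %*% s, symmetric = TRUE)$values, decreasing = TRUE)
  ev <- ev[seq_along(res$inertia)]
  expect_equal(res$inertia, ev, tolerance = 1e-10)
  expect_equal(sum(res$percent_inertia), 100, tolerance = 1e-10)
  expect_equal(res$total_inertia, sum(s^2), tolerance = 1e-12)
  # axes ranked by inertia
  expect_true(all(diff(res$inertia) <= 1e-12))
})

test_that("correspondence analysis agrees with an independent implementation", {
  skip_if_not_installed("MASS")
  set.seed(41)
  x <- matrix(rpois(60, 12) + 1, nrow = 6)
  res <- correspondence_analysis(x)
  mc <- MASS::corresp(x, nf = min(dim(x)) - 1)
  expect_equal(res$inertia, unname(mc$cor^2), tolerance = 1e-8)
  # principal row coordinates match up to sign
  ours <- res$row_coords
  theirs <- mc$rscore %*% diag(mc$cor)
  for (k in seq_len(ncol(ours))) {
    expect_equal(abs(ours[, k]), unname(abs(theirs[, k])), tolerance = 1e-6)
  }
})

test_that("degenerate CoA inputs are handled as defined", {
  same <- matrix(rep(c(3, 1, 6), each = 4), nrow = 4)
  res <- correspondence_analysis(same)
  expect_equal(res$total_inertia, 0)
  expect_equal(length(res$inertia), 0L)

  # rank-1 perturbation concentrates inertia on axis 1
  base <- c(5, 10, 15, 20)
  t_i <- seq(-0.3, 0.3, length.out = 10)
  pert <- outer(rep(1, 10), base) * (1 + outer(t_i, c(1, -1, 1, -1)) * 0.2)
  res1 <- correspondence_analysis(pert)
  expect_gt(res1$percent_inertia[1], 99)

  expect_warning(correspondence_analysis(rbind(c(1, 2, 0), c(2, 1, 0),
                                               c(0, 0, 0))),
                 "dropped")
})

test_that("GC class labels use left-closed boundaries", {
  expect_equal(as.character(gc_class_labels(c(0.449, 0.45, 0.599, 0.60, 0.80))),
               c("low", "mid", "mid", "high", "high"))
})
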