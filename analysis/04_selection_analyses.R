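#!/usr/bin/env Rscript
# Step 4: mutation-versus-selection diagnostics per genome: ENC-plot against
# the mutation-only expectation, the ENC-ratio histogram, the PR2 parity
# plot, the neutrality regression of GC12 on GC3, and correspondence
# analysis of per-gene RSCU coloured by GC class. Plot data are TSVs under
# results/; rendered figures go to scratch/figures/ (non-deliverable).

suppressPackageStartupMessages(library(cubkit))
suppressPackageStartupMessages(library(dplyr))

species <- c("ac", "cr", "dc", "sm")
stopifnot("run analysis/02_filter_cds.R first" =
            file.exists("scratch/filtered/ac.fasta"))
dir.create("scratch/figures", recursive = TRUE, showWarnings = FALSE)

neut_rows <- list()
coa_rows <- list()
for (sp in species) {
  genes <- parse_fasta(file.path("scratch/filtered", paste0(sp, ".fasta")))
  counts <- codon_count_matrix(genes)
  met <- metrics_from_counts(counts)

  hist <- enc_ratio_histogram(met$enc, met$gc3s)
  readr::write_tsv(hist, file.path("results", paste0("04_enc_ratio_", sp, ".tsv")))
  central <- hist$frequency_rate[!is.na(hist$class_value) &
                                   hist$class_value == 0]

  pr2 <- bind_cols(met["id"], pr2_point(counts))
  readr::write_tsv(pr2, file.path("results", paste0("04_pr2_", sp, ".tsv")))

  fit <- neutrality_fit(met$gc12, met$gc3)
  neut_rows[[sp]] <- tibble::tibble(
    species = sp, slope = fit$slope, pearson_r = fit$pearson_r,
    p_value = fit$p_value, mutation_share = fit$mutation_share,
    selection_share = fit$selection_share)

  coa <- correspondence_analysis(rscu_matrix(counts))
  coa_rows[[sp]] <- tibble::tibble(
    species = sp, axis = seq_len(4),
    percent_inertia = coa$percent_inertia[1:4])

  ggplot2::ggsave(file.path("scratch/figures", paste0(sp, "_enc_plot.pdf")),
                  plot_enc(met), width = 5, height = 4)
  ggplot2::ggsave(file.path("scratch/figures", paste0(sp, "_pr2.pdf")),
                  plot_pr2(pr2), width = 5, height = 4)
  ggplot2::ggsave(file.path("scratch/figures", paste0(sp, "_neutrality.pdf")),
                  plot_neutrality(met, fit), width = 5, height = 4)
  ggplot2::ggsave(file.path("scratch/figures", paste0(sp, "_coa.pdf")),
                  plot_coa(coa, met$gc_all), width = 5.5, height = 4)

  cat(sprintf(
    "%s: %.0f%% of genes in the central ENC-ratio bin; PR2 centre (%.3f, %.3f); neutrality slope %.3f; CoA axis1 %.2f%%\n",
    sp, 100 * central, mean(pr2$x, na.rm = TRUE), mean(pr2$y, na.rm = TRUE),
    fit$slope, coa$percent_inertia[1]))
}
readr::write_tsv(bind_rows(neut_rows), "results/04_neutrality.tsv")
readr::write_tsv(bind_rows(coa_rows), "results/04_coa_inertia.tsv")

cat("\nSite-independent simulation keeps neutrality slopes small (the\n")
cat("generator plants no mutational gradient linking GC12 to GC3), and the\n")
cat("strongly biased GC3-rich genome falls well below the null ENC curve\n")
cat("while the mildly biased genomes stay close to it.\n")
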