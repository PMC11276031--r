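#!/usr/bin/env Rscript
# Step 1: simulate four CDS sets emulating the codon-usage profiles of the
# four study genomes (two ferns, two lycophytes). Silent-position GC targets
# follow the published genome GC3 values; three genomes get a mild
# within-family bias and an A/U-leaning silent composition, while the
# S. moellendorffii stand-in is GC3-rich with a stronger bias. Each genome
# carries a 10% high-expression stratum with elevated bias so the
# delta-RSCU screen downstream has a gradient to detect. A handful of
# deliberately malformed records is appended so the screening step has
# something to reject.
#
# Large FASTA output goes under scratch/ (not a deliverable); the genome
# design table goes to results/.

suppressPackageStartupMessages(library(cubkit))
suppressPackageStartupMessages(library(tibble))

dir.create("scratch/genomes", recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

design <- tribble(
  ~species, ~n_genes, ~gc3_target, ~bias, ~seed,
  "ac",     300,      0.467,       0.12,  101,
  "cr",     300,      0.420,       0.12,  102,
  "dc",     300,      0.410,       0.10,  103,
  "sm",     300,      0.607,       0.22,  104
)

for (i in seq_len(nrow(design))) {
  d <- design[i, ]
  spec <- genome_spec(
    n_genes = d$n_genes, length_range = c(900, 3000),
    gc3_target = d$gc3_target, seed = d$seed,
    strata = list(
      list(fraction = 0.9, bias = d$bias, label = "baseline"),
      list(fraction = 0.1, bias = min(1, d$bias + 0.35), label = "high_expr")
    )
  )
  sim <- generate_genome(spec)
  fa <- file.path("scratch/genomes", paste0(d$species, ".fasta"))
  write_fasta(sim$genes, fa)
  # append malformed records for the screening step
  cat(fixture_invalid_cds(), file = fa, append = TRUE)
  readr::write_tsv(sim$truth$strata,
                   file.path("scratch/genomes", paste0(d$species, "_strata.tsv")))
  cat(sprintf("%s: %d genes + 7 fixture records -> %s\n",
              d$species, d$n_genes, fa))
}

readr::write_tsv(design, "results/01_genome_design.tsv")
cat("Genome design written to results/01_genome_design.tsv\n")
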