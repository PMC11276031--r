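Package: cubkit
Title: Genome-Wide Codon Usage Bias Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide codon usage bias analysis of coding
    sequence (CDS) sets: CDS quality screening, codon counting, relative
    synonymous codon usage (RSCU) under standard or split degeneracy-family
    schemes, Wright's effective number of codons (ENC) with the ENC-plot
    expected curve and ENC-ratio histogram, positional and silent-site base
    composition, CAI/CBI/Fop adaptation indices, PR2 parity analysis,
    neutrality (GC12 on GC3) regression, correspondence analysis of per-gene
    RSCU, optimal-codon screening by delta-RSCU between expression groups,
    Kazusa-style codon frequency table comparison between species, and a
    seeded synthetic CDS generator with known statistical structure for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
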