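---
title: "Genome-wide codon usage bias analysis with cubkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-wide codon usage bias analysis with cubkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cubkit)
```

## The problem

Synonymous codons are not used uniformly. In a genome, the balance between
mutation pressure (which shifts base composition at all sites, most visibly
at silent third positions) and natural selection (which favours particular
codons, typically in highly expressed genes) leaves quantifiable traces in
codon counts. `cubkit` implements the standard battery of diagnostics used
to read those traces from a set of coding sequences (CDS): composition
indices, RSCU, ENC and its null curve, PR2 parity, the neutrality
regression, correspondence analysis, and the delta-RSCU optimal-codon
screen. The motivating application is the comparison of fern and lycophyte
nuclear genomes (*Adiantum capillus-veneris*, *Ceratopteris richardii*,
*Diphasiastrum complanatum*, *Selaginella moellendorffii*), whose pooled
codon counts ship with the package, but every function is generic over any
CDS FASTA.

## CDS screening

Whole-genome CDS annotations contain fragments and miscalled models, so
sequences are screened before any statistic is computed. A CDS is kept iff,
checked in this fixed order: (1) its length is a multiple of 3; (2) it is at
least 300 nt long, start and stop included; (3) it contains only A/C/G/U
(ambiguity codes are not resolved); (4) it starts with AUG; (5) it ends with
UAA, UAG or UGA; (6) it has no in-frame internal stop. The order is fixed so
that the reported reason code — always the *first* failing rule — is
deterministic. Sequences are held internally in the RNA alphabet (T read as
U) because codons are reported as RNA triplets throughout. The 300 nt
threshold is read as including the start and stop codons; the interpretation
is configurable via `min_len`.

## RSCU and the two family schemes

For codon $j$ in a synonymous family $i$ of size $n_i$ with counts $x_{ij}$,

$$\mathrm{RSCU}_{ij} = \frac{x_{ij}}{\tfrac{1}{n_i}\sum_j x_{ij}},$$

the observed count relative to uniform within-family usage; values above 1
mark high-frequency codons. Two family schemes are provided. `"standard"`
treats Leu, Ser and Arg as six-fold families. `"split"` divides each of
them into a four-fold and a two-fold subfamily (CUN + UUR, UCN + AGY,
CGN + AGR), which is how tools in the CodonW lineage tabulate RSCU.
`"split"` is the default because the published genome-wide RSCU tables for
the four study species are reproduced from their printed counts *only*
under that scheme: for example, Leu CUU in *A. capillus-veneris* gives
1.502 under split but 1.475 under the six-fold treatment, and the printed
value is 1.502. The exact-reproduction check in the test suite compares all
244 printed cells at their printed precision.

Two aggregation modes are exposed and deliberately distinct: genome-level
index tables are arithmetic means of per-gene values, while genome RSCU is
computed from pooled counts. The pooled RSCU of a genome equals the RSCU of
the pooled counts, not the mean of per-gene RSCU rows; both facts are
tested. Families with zero total count yield `NA`, never 0.

## ENC and its null curve

Wright's effective number of codons for a gene uses, per amino acid with
total usage $n \ge 2$ and usage fractions $p_i$, the homozygosity estimate
$F = (n\sum p_i^2 - 1)/(n-1)$, averaged within the degeneracy classes of
the standard code, then

$$\mathrm{ENC} = 2 + \frac{9}{\bar F_2} + \frac{1}{\bar F_3} +
\frac{5}{\bar F_4} + \frac{3}{\bar F_6},$$

capped at 61 (uniform usage; 20 means one codon per amino acid). ENC always
uses the standard six-fold classes regardless of the RSCU scheme. Numerical
choices, where the literature is silent: an absent three-fold class mean is
imputed as $(\bar F_2 + \bar F_4)/2$ and an absent six-fold mean as
$\bar F_4$; amino acids with $n < 2$, or with a non-positive $F$ estimate
(which carries no usable information at small counts), are excluded from
class means; a gene missing its two-fold or four-fold class entirely is
reported `NA`.

The mutation-only expectation at silent GC content $s$ is
$\mathrm{ENC}_{exp} = 2 + s + 29/(s^2 + (1-s)^2)$. Note that because of the
linear $+s$ term the curve's true maximum is 60.5011 at $s \approx 0.517$,
marginally above $\mathrm{ENC}_{exp}(0.5) = 60.5$; the tests assert the
closed-form values at $s \in \{0, 0.5, 1\}$. Deviations are summarised by
the ENC ratio $(\mathrm{ENC}_{exp} - \mathrm{ENC}_{obs})/\mathrm{ENC}_{exp}$,
binned into eight width-0.1 classes from $-0.25$ to $0.55$; genes outside
the range go to an explicit overflow row rather than being dropped.

## Composition, PR2 and the neutrality regression

Positional GC (GC1/GC2/GC3) is computed over sense codons with stops
excluded; GC12 and GCall are the derived means and are held to their
defining identities to 1e-12. Silent-site composition (A3s/T3s/C3s/G3s,
GC3s) is restricted to codons of degenerate families and follows the CodonW
convention: each base fraction is divided by the silent third positions at
which that base is *possible*, so the four fractions need not sum to one.

PR2 coordinates are $G_3/(G_3+C_3)$ against $A_3/(A_3+T_3)$ per gene,
computed by default over all sense-codon third positions excluding AUG and
UGG; a four-fold-family-only mode is available since usage differs among
authors, and the default is the more inclusive one. The neutrality fit is
an unweighted OLS of GC12 on GC3 (no weighting is established for this
diagnostic); the conventional reading reports $|slope|\cdot 100\%$ as the
mutation share, and the result flags negative slopes explicitly because the
absolute-value reading is then doing real work.

## Correspondence analysis

CoA is run on the genes x 59 per-gene RSCU matrix (count input is accepted
for the count-based variant). With $P$ the relative-frequency matrix and
$r, c$ its margins, the standardized residuals
$S = D_r^{-1/2}(P - rc^{\top})D_c^{-1/2}$ are decomposed by SVD; axis
inertia is the squared singular value, reported as a percentage of total
inertia, and coordinates are principal (mass-standardised and scaled by the
singular values). The implementation is a dozen lines of base linear
algebra because the contract pins the exact decomposition; the test suite
cross-checks inertias and coordinates against an independent dense
eigendecomposition and against `MASS::corresp` to 1e-8. `NA` RSCU cells
(genes missing a family) enter as zero usage; all-zero rows and columns are
dropped with a warning.

## Expression groups and the optimal-codon screen

"Expression" is proxied by ENC extremes: the 10% of genes with the lowest
ENC form the high-expression group. Read literally, the source protocol
assigns the *highest*-ENC decile to high expression, which inverts the
established extreme-ENC convention; the default here follows the
convention, and `direction = "literal"` restores the literal reading. The
choice cannot affect the published desk-scale targets, which depend only on
pooled RSCU. Ties at the cutoff are broken by gene id so groups are
deterministic and always disjoint.

The screen computes group RSCU from pooled within-group counts (not means
of per-gene RSCU), takes $\Delta\mathrm{RSCU} = \mathrm{RSCU}_{high} -
\mathrm{RSCU}_{low}$, and flags as optimal the codons with
$\Delta\mathrm{RSCU} \ge 0.08$ (inclusive), $\mathrm{RSCU}_{high} > 1$, and
pooled genome RSCU > 1.

## Cross-species comparison

Codon usage is compared between genomes on frequencies per 1000 codons
(the native unit of Codon Usage Database flat files, which
`parse_kazusa()` reads in either DNA or RNA spelling, including the
counts-only variant). A codon whose frequency ratio is $\ge 2$ or
$\le 0.5$ (inclusive) is flagged; the verdict is "similar" iff no
synonymous codon is flagged. Stop codons are excluded from the summary;
AUG and UGG appear in the table but are marked non-synonymous. An
RSCU-ratio comparison can be assembled from `rscu()` output if wanted, but
per-1000 frequency is the primary mode.

## The synthetic genome generator

Real genome downloads are deliberately out of scope, so validation runs on
generated CDS sets whose truth is known exactly. `generate_genome()` draws
each gene as AUG + i.i.d. body codons + a uniform stop. Body codons follow
amino-acid weights (default uniform over the 20) times within-family
preferences, parameterised either by a scalar bias $b$ (0 = uniform, 1 =
single codon per family) or by explicit preference vectors; an optional
GC3 target is met by exponentially tilting third-position G/C odds within
families, solved by root finding, with unreachable targets rejected.
Strata with distinct preferences provide an expression-linked gradient
with a planted truth. A companion generator,
`generate_mutation_genome()`, draws codons from a mutation-only
base-composition model with a per-gene GC gradient and records exact
expected positional GC per gene, giving an oracle for the neutrality
slope.

What the generator emulates: length distributions (in-frame, >= 300 nt),
start/stop structure, within-family preference, silent-position GC level,
and expression strata. What it does not emulate: codon-pair and
dinucleotide structure, amino-acid composition varying across genes,
introns/UTRs, and any mutation-selection population process. Every
statistic in this package is a single-codon statistic, so site-independent
sampling is sufficient for validity checks — but a pass on synthetic data
says nothing about, e.g., dinucleotide-driven biases in real genomes.

## Test design and problem sizes

Stochastic checks fix their seeds and use sizes chosen in advance so that
the asserted tolerance sits about four standard errors from the null:
pooled RSCU converging to 1 within ±0.05 is checked at 800 genes x 500
codons (~2.4e5 codons, ~1.2e4 per family); planted-optimal-codon recovery
is checked at 2000 genes x 1500 codons, where the 0.08 delta-RSCU
threshold is ≈4 sigma of null delta noise in a four-fold family, so the
screen recovers exactly the two planted codons and nothing else; the
neutrality slope is recovered within ±0.05 on 500 genes of 600–1500 codons
against the exact-expectation oracle (gene-level GC3 sampling noise
attenuates the OLS slope by ~1–2%, well inside the band). PR2 parity
centring is checked on genomes restricted to four-fold families, the case
where uniform within-family usage is exactly strand-symmetric at third
positions; across the whole code table the uniform-usage centre is not
(0.5, 0.5), because stop/start exclusions make the third-base inventory
asymmetric, and the corresponding test asserts the code-table expectation
instead.

## Known limitations

* The CAI reference set is not specified by the motivating protocol; the
  default is the lowest-ENC decile of the same genome (weight floor 0.01
  for zero-count codons), overridable by explicit weights. CAI values are
  therefore internally referenced and not comparable across genomes
  without a common reference.
* CBI/Fop need an optimal-codon set; the default chain (delta-RSCU screen,
  falling back to pooled high-frequency codons for small gene sets) is a
  convention, and published CBI/Fop values computed against organism-
  specific curated sets will differ.
* Genome-scale published quantities (per-genome index tables, ENC < 35
  gene counts, neutrality slopes, CoA axis percentages, optimal-codon
  lists) depend on the full genome downloads and are not reproduced at
  desk scale; the package reproduces the printed pooled-count tables
  exactly and covers the genome-scale machinery with property-based checks
  on synthetic data.
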