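---
title: "Codon usage bias and divergence in mitochondrial genomes: methods"
author: "mitocodon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon usage bias and divergence in mitochondrial genomes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocodon)
```

# Scope and data model

`mitocodon` analyses sets of annotated vertebrate mitochondrial genomes: the
13 protein-coding genes (PCGs), 22 tRNAs, two rRNAs, the control region and
the light-strand replication origin. Three S4 classes carry the data:

* `MitogenomeRecord` — one circular genome with a typed feature table.
  Coordinates are 1-based inclusive on the heavy strand; a feature with
  `start > end` wraps the origin of the circle. Per-feature sequences are
  stored in coding orientation (light-strand features already
  reverse-complemented), so extraction is an involution: reverse-complement
  of an L-strand feature sequence is exactly the genome subsequence.
* `CodonCountTable` — 64 codon counts for one gene (or a pooled set), tied
  to the `GeneticCode` they were counted under.
* `AlignmentBlock` — equal-length homologous sequences for one gene across
  taxa; codon-framed blocks additionally guarantee a width divisible by
  three.

The `GeneticCode` class wraps an NCBI translation table with the derived
synonymous-family partition. Under the default vertebrate mitochondrial code
(table 2), `TGA` is Trp, `ATA` is Met and `AGA`/`AGG` are stops, so the
family structure differs from the standard code in ways the statistics must
respect: there are no single-codon families, Arg is four-fold, and Met and
Trp are two-fold.

# Parsing and validation

GenBank flat files are parsed directly (single circular records with
CDS/tRNA/rRNA/D-loop/rep_origin features; `complement()` and origin-spanning
`join()` locations supported). Gene names are normalized onto one controlled
vocabulary (`ND2` → `NAD2`, `COI` → `COX1`, `cob` → `CYTB`, ...); unmapped
names warn and are kept verbatim, never dropped. `D-loop`/`misc_feature`
annotations are labelled as the control region.

Mitochondrial CDS frequently end in the incomplete stops `T` or `TA`, which
polyadenylation completes to `TAA` in the transcript. `completeStop()`
reproduces this: a trailing `T` (length mod 3 = 1) gains `AA`, a trailing
`TA` (mod 3 = 2) gains `A`, anything else with a broken frame is an error.
`extractCDS()` then validates every gene: length divisible by three, start
codon in the policy set, and no internal stop. The default start policy is
permissive (`ATG`, `GTG`), reflecting the GTG-initiated COX1 common in fish
mitogenomes; pass `starts = "ATG"` for strict checking. Initiation codons
are counted as written in all downstream statistics (no forced-Met
recoding); the effect is at most one codon per gene.

# Composition statistics

Strand skews follow the standard definitions AT-skew = (A − T)/(A + T) and
GC-skew = (G − C)/(G + C), computed over unambiguous bases only (ambiguity
codes are tallied separately and excluded from numerator and denominator).
Codon-position composition pools all codons of a CDS set and reports GC1,
GC2, GC3 and GC12 = (GC1 + GC2)/2; stop codons are excluded from pooling by
default, consistent with the index computations (a flag includes them).
Fractions are computed internally; reports format percentages with two
decimals.

# The codon-usage index battery

All indices are computed per gene and tied to the active code's family
structure:

* **RSCU**: observed count divided by the uniform-synonym expectation;
  family values sum to the degeneracy exactly (a property the tests enforce
  on random tables).
* **ENC**: Wright's homozygosity estimator generalized to the code's
  degeneracy classes. Per family with sample size $n > 1$,
  $\hat F = (n\sum p_i^2 - 1)/(n-1)$; class averages use families with
  defined, positive $\hat F$; an empty class is imputed $\bar F_k = 1/k$;
  the result is clamped to [20, 61] and clamping is recorded. Under table 2
  the theoretical maximum is 60 (12/½ + 6/¼ + 2/⅙), reached at uniform
  usage; under the standard code the familiar limits 61 (uniform) and 20
  (one codon per amino acid) hold, which the tests assert.
* **GC3s / A3s / T3s / G3s / C3s**: third-position base frequencies over
  codons of synonymous families, stops excluded, all five sharing one
  denominator (so A3s + T3s + G3s + C3s = 1). The classical "exclude Met,
  Trp and stops" wording presumes the standard code; under table 2 Met and
  Trp are two-fold families and are therefore retained. A
  `legacyExclude = c("M", "W")` argument reproduces tool-lineage behaviour
  where comparability matters.
* **CAI**: geometric mean of relative-adaptiveness weights
  $w = RSCU/\max RSCU$ per family, restricted to multi-synonym codons.
  Because mitochondrial genomes offer no independent high-expression gene
  set, the default reference is the pooled 13-PCG usage of all taxa in the
  run (self-referential); any weight table can be supplied. Codons unused
  in the reference receive a floor weight of 0.01 (configurable), with a
  warning.
* **CBI / FOP**: the optimal set defaults to the highest-RSCU codon of each
  family in the reference (ties broken alphabetically for determinism).
  FOP is the optimal fraction; CBI rescales against the uniform-usage
  expectation so that random usage scores 0 and exclusive optimal usage 1.
* **GRAVY / AROMO**: mean Kyte–Doolittle hydropathy and the Phe/Tyr/Trp
  fraction of the translated protein, terminal stop excluded.

# Bias diagnostics

The neutrality plot regresses GC12 on GC3 across genes by ordinary least
squares; the slope estimates the mutation-pressure share of codon-usage
variance and its two-sided t-test p-value is reported without
multiple-testing correction (a handful of independent per-species fits).
The ENC–GC3s null curve $ENC = 2 + s + 29/(s^2 + (1-s)^2)$ gives the
expectation under mutation pressure alone (maximum 60.5 at $s = 0.5$,
symmetric in $s \leftrightarrow 1-s$); per-gene deviations
$(ENC_{exp} - ENC_{obs})/ENC_{exp}$ quantify how far genes fall below it.
PR2 coordinates are $x = G_3/(G_3+C_3)$, $y = A_3/(A_3+T_3)$; the default
stratum is the fully degenerate (fourfold) codon boxes, the classical PR2
choice, with `all_synonymous` available for comparability. Quadrants follow
the mathematical convention around (0.5, 0.5); exact ties are reported as
`boundary`, not silently assigned.

For optimal-codon classification the high- and low-bias gene groups are not
externally given, so the package ranks the 13 genes by ENC and takes the
lowest-ENC quartile (3 genes) as the high-bias (high-expression proxy)
group and the highest-ENC quartile as the low group; the ranking key (ENC
or CAI) and group size are options recorded in the output metadata.
ΔRSCU = RSCU(high) − RSCU(low); codons with overall RSCU > 1 are
high-frequency, ΔRSCU > 0.08 marks high-expression codons, and both
together mark optimal codons — the hierarchy optimal ⊆ HFC ∩
high-expression is enforced as an invariant.

# Divergence statistics

Nucleotide diversity is Nei's π: the mean pairwise proportion of differing
sites, with complete deletion of unresolved columns by default (pairwise
deletion available). K2P distances separate transition (P) and transversion
(Q) proportions, $d = -\tfrac12\ln(1-2P-Q) - \tfrac14\ln(1-2Q)$, with
pairwise deletion and explicit saturation flagging.

Ka and Ks use the original Nei–Gojobori proportional method. One choice
deserves emphasis: potential-site counting at each codon position takes the
synonymous fraction *among non-stop single-base changes*, redistributing
stop-bound mutations pro rata. This keeps S + N = 3 × (codons compared)
exactly — an invariant the tests assert — and matches biological reality
(and the package's own simulator), where mutations into stop codons do not
fix. Observed differences at codons differing in more than one position are
averaged over all shortest substitution pathways, excluding pathways
through stop codons (all pathways are used only if every one is blocked).
Proportions receive the Jukes–Cantor correction; values at or beyond the
3/4 limit are flagged undefined rather than clamped. The Table-1-style
summary averages per-pair values arithmetically; for Ka/Ks the default is
the mean of defined per-pair ratios ("average Ka/Ks"), with ratio-of-means
as an alternative switch, since either convention is defensible.

# Supermatrix construction

The five standard concatenations are built from per-gene blocks in a fixed
canonical order (ATP6, ATP8, COX1–3, CYTB, NAD1–6, NAD4L, rRNAs, tRNAs
alphabetically) so outputs diff cleanly: `PCGs`, `PCGs12` (third codon
positions excluded — retaining exactly 2/3 of codon sites, e.g. an
11,388-site matrix reduces to 7,592), `PCGsRNA`, `PCGs12RNA`, and `Mt`
(approximated as the annotated partitions including control region and OL;
whole-genome alignment is out of scope). Published site counts additionally
depend on alignment-trimming settings that are rarely reported, so the
package targets the structural relationships and records provenance: every
output column is traceable to its source column, and the partition table
tiles the matrix exactly. A simple gap-fraction trimmer (whole codons
dropped in framed blocks; idempotent) stands in for heavier trimming tools,
which remain external, as do alignment, model selection and tree inference.
Output formats are relaxed PHYLIP and NEXUS with a `sets` block of
charsets.

# The simulator and what it does (and does not) emulate

`simulateCdsFamily()` generates homologous CDS families on a star tree.
Root codons are drawn by sampling the third base from the target
distribution (GC3 and skews) and then a first-two-base box among sense
codons, so the realized third-position marginal matches the target exactly
— with at least 3,000 codons the realized GC3 sits within ±0.02 of the
target. Evolution is a per-codon-site continuous-time chain with relative
rates $\kappa^{ts}\,\omega^{nonsyn}$ and substitutions into stops
forbidden, normalized by the root sequence's mean leaving rate so that the
branch length is expected substitutions per nucleotide site. The `d`
parameter is the expected *pairwise* divergence (tips sit at d/2 from the
root). The star tree isolates pairwise divergence from tree shape, keeping
closed-form expectations simple.

Defaults mirror a small clade of anchovy-like fish mitogenomes: 7 taxa,
the 13 PCGs at their typical lengths (about 3,800 codons, ATP8 shortest at
55 codons, NAD5 longest at 611), GC3 = 0.405 with A-rich, C-over-G third
positions, κ = 2, ω = 0.05, d = 0.2. `emitGenBank()` wraps the simulated
genes into fully annotated circular records — standard gene order, NAD6
and 8 tRNAs on the light strand, GTG-initiated COX1, a truncated-stop
COX2, taxon-varying control-region lengths, and a rotation that makes the
control region span the origin — exercising every parsing path.

What the simulator deliberately does **not** emulate: indels (alignment is
external), rate heterogeneity across sites, realistic tRNA/rRNA evolution,
amino-acid hydrophobicity structure (first and second codon positions are
uniform, so simulated GRAVY values are near zero rather than positive as
in real membrane-protein-rich mitogenomes), and non-stationary
composition. Passing recovery tests therefore demonstrates estimator
correctness under the stated model, not robustness to every property of
real data.

# Calibration choices

Two recovery checks fix parameters the model leaves open, chosen on
methodological grounds:

* K2P recovery runs at ω = 1. A nucleotide-distance calibration needs a
  selection-free codon process; with purifying selection the
  position-heterogeneous rates violate K2P's homogeneity assumption by
  design. At 5,000 codons, pairwise d = 0.2 and κ = 2, the mean pairwise
  estimate falls within three standard errors (Kimura's large-sample
  variance) of the truth.
* Ka/Ks recovery runs at κ = 1 because the proportional Nei–Gojobori
  method counts potential sites without transition weighting; with κ = 1
  the site counting is exactly calibrated to the generating process and
  the check isolates ω recovery. Across ω ∈ {0.05, 0.2, 0.5} (20
  replicates of 5,000 codons at d = 0.2) the mean estimate stays within
  15% of the truth. With ω = 0 the truth record contains no nonsynonymous
  events, while the Ka *estimate* is near — not exactly — zero: pathway
  averaging at codons hit more than once attributes fractional
  nonsynonymous steps (Ka on the order of $10^{-3}$, versus Ks near 0.8).

Problem sizes throughout the test-suite and acceptance computations (3–7
taxa, 50–5,000 codons per gene, 10–20 replicates) were chosen as the
smallest sizes at which the Monte-Carlo error bands above are meaningful.

# Numerical and degenerate-input conventions

Empty or all-ambiguous sequences, empty PR2 strata, zero-variance
regressors, saturated distances and empty codon families are flagged or
raised as errors — never silently converted to zero. ENC clamping events
are recorded on the returned value. All report tables are UTF-8 TSV with
numeric columns fixed at four decimals, so reruns are byte-identical and
diffs are meaningful; the run manifest records the package version, every
analytic option and a configuration hash.

# Known limitations

Accession-to-taxon mapping for public records must be user-supplied (the
annotation itself rarely identifies the species reliably). Genes of unequal
length across taxa are truncated to the shortest for divergence summaries
with a warning — a crude stand-in for proper alignment, which is external.
The optimal-codon group construction (ENC quartiles) is one reasonable
choice among several; published optimal-codon counts are sensitive to the
unreported grouping used elsewhere and should not be compared digit for
digit.
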