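---
title: "Methods: pooled TILLING screen simulation, detection and deconvolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled TILLING screen simulation, detection and deconvolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gridtill)
```

This vignette documents the statistical model behind gridtill, the
parameters that matter, the numerical conventions, and the design choices
made where the design was genuinely open. It states no empirical result
that the package's tests and acceptance script do not themselves compute.

## The screen model

A two-dimensionally pooled TILLING screen arranges the plants of a
mutagenised population in complete `n_rows × n_cols` grids (blocks).
Equal amounts of tissue from every plant in a row are pooled into one
sequencing library, and likewise along columns, so a block of 16 × 16
plants is screened twice in 32 libraries. The whole analysis rests on two
facts:

1. **Dosage.** In an equimolar pool of $N$ diploid plants, a carrier
   contributes $d$ of the $2N$ chromosomes, $d = 1$ (heterozygous) or
   $d = 2$ (homozygous). The expected pooled alternate-read fraction is
   $f = d/(2N)$: 1/32 and 1/16 at $N = 16$.
2. **Intersection.** Each plant sits in exactly one row pool and one
   column pool, so a genuine induced mutation is seen in exactly two
   libraries of its block, and their intersection is a single plant.

Everything else — thresholds, zygosity boundaries, failure handling — is
bookkeeping around these two facts.

## The synthetic-data generator

`simulate_population()` + `simulate_pool_counts()` generate the inputs
the downstream modules consume. The defaults are the study conditions of
a heavily mutagenised diploid (barley-like) population:

| parameter | default | meaning |
|---|---|---|
| `mutation_rate` | 1/154000 per bp per plant | one induced mutation per 154 kb |
| `spectrum` | 79.4 / 8.1 / 6.8 / 3.9 / 1.8 % | strand-collapsed classes G/C→A/T, A/T→T/A, G/C→T/A, A/T→G/C, other |
| `het_fraction` | 0.6 | heterozygous share of induced mutations |
| `depth` | 10 000 reads/pool/site | pooled amplicon coverage |
| `error_rate` | 10⁻³ | per-base miscall probability |
| `imbalance` | 0 | per-plant contribution dispersion (0 = equimolar) |

Mutation counts per plant are Poisson(rate × total target bp). Each
mutation draws a class from the spectrum and is then placed uniformly
over the bases *eligible* for that class (a G/C→A/T event only on G or
C), by rejection sampling; the alternate base follows deterministically
from the reference base and class, with the `other` class covering the
two remaining strand-collapsed transversions (G/C→C/G, A/T→C/G).
Zygosity is Bernoulli(`het_fraction`); the observed 60/40 het/hom split
of a twice-mutagenised, once-selfed population is taken as a free
parameter rather than derived from pedigree.

Pooled counts at each (pool, site) are multinomial over the four bases
with a Poisson(`depth`) total. The base probabilities are the dosage
fractions $f$ perturbed by a symmetric error model (each read miscalled
to one of the three other bases with probability $e/3$). Pool imbalance,
when enabled, draws member weights from a Dirichlet with concentration
$1/\text{imbalance}$ — a one-parameter way to produce the sub-equimolar
carrier fractions (heterozygotes below 0.03 rather than at 0.03125) seen
in real pools. Whole-library failure is modelled separately
(`inject_pool_failure()`) as binomial thinning of a pool to a residual
total read count, because real failures are library-level events, not
per-site ones.

**Default depth and failure threshold.** Real pooled amplicon libraries
in this design carry on the order of 10⁵ reads over a few kb of targets,
i.e. roughly 10⁴ reads per site per pool — hence `depth = 10000`. Failed
libraries are catastrophic (hundreds of reads rather than ~10⁵), so any
total below 1 000 reads (`min_pool_depth`) is treated as failed; the
choice is insensitive over two orders of magnitude because real totals
are bimodal.

**Sibling duplicates** (plants from one bulk-harvested parent sharing a
mutation set) are produced by `clone_siblings()`, which copies a donor's
mutations verbatim, so that duplicate collapse has something real to do.

**Reproducibility.** A master seed drives everything; pooled counts use
one substream per block (`seed + 1000 + block`), so blocks can be
regenerated independently and in any order.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: PCR chimeras and amplicon-specific dropout
(only whole-pool failure is modelled), mapping and base-quality
artefacts, the RGC site preference of EMS, non-uniform base composition,
outcrossing, and indels (the screen analyses SNVs only). Recovery rates
measured on simulated data are therefore upper bounds for real screens
with imperfect libraries.

## Detection

`detect_pool_variants()` emits a hit for a (pool, site, alternate) iff
`alt_count ≥ min_alt_total` (30) **and** `alt_count/depth ≥
min_alt_fraction` (0.02) **and** the pool's total reads ≥
`min_pool_depth`. Both comparisons are `≥`, matching the "minimum"
semantics of pooled callers. The 0.02 default accepts 1 alternate
chromosome in 50 against the expected 1 in 32 — a deliberate margin for
imbalanced pools. For pool sizes other than 16 the same margin is kept:
`(2/3)/(2N)`; at `N = 16` the frozen value is exactly 0.02.

The EMS filter (G→A / C→T only) is applied **before** deconvolution by
`run_pipeline()`. The ordering is exposed (the filter is a separate
function) because either order is defensible; applying it first means
non-EMS sequencing artefacts can never create crossed intersections.

Hits inside failed libraries are suppressed at detection time, and the
failure is passed explicitly to deconvolution — a silent drop would look
identical to "no mutation", which is exactly the trap a failed library
sets: it removes the ability to detect mutations in all plants of its
axis.

## Deconvolution and zygosity

`deconvolve_block()` groups hits by variant and applies the
twice-per-block rule: exactly one row and one column hit → `confirmed`
at the intersection; hits on one axis only → `row_only`/`column_only`
(rejected — the rule's whole point is that singles are noise); one axis
hit while the other axis contains a failed library → `undetermined`
(reported, not dropped — visibility is the remedy for failed libraries);
two or more pools with both axes represented → `ambiguous`, listing
every intersection. Two same-site variants with different carriers
produce crossed intersections that the strict rule cannot distinguish;
they are reported ambiguous rather than resolved by fraction matching,
which would be invention. The implementation is tested for exact
agreement with a brute-force oracle that enumerates all plants, over all
2^(r+c) hit patterns on grids up to 4 × 4.

Zygosity for confirmed calls uses the depth-weighted mean of the two
pooled fractions against the midpoint boundary $3/(4N)$ (0.046875 at
$N = 16$) between the heterozygous ($1/2N$) and homozygous ($1/N$)
expectations. The boundary is this package's decision rule — real screens
validated zygosity by Sanger sequencing but published no numeric rule;
the midpoint is the maximum-margin separator between the two
expectations, and ties (exactly at the boundary) break to heterozygous,
the more common class. At depth 10⁴ the binomial scatter of a pooled
fraction is ≈ 0.0017, an order of magnitude below the gap to the
boundary, which is why zygosity accuracy is essentially 1 in the
acceptance suite.

`collapse_duplicates()` groups calls by (target, position, ref, alt) and
returns one record per distinct variant with its carrier list; the same
variant confirmed in different blocks stays distinct at the call level
(different plants) and merges only here. The operation is idempotent.

## Effect annotation

`annotate_variant()` assigns exactly one category per (variant, gene
model) with precedence splice site > CDS effect > UTR > intron > flank >
intergenic. Splice sites are the first/last 2 intronic bases (canonical
GT/AG — the SnpEff convention). CDS effects are computed by translating
the affected codon on the coding strand (reverse-complemented for minus
strand genes): stop gained → nonsense, amino-acid change → missense,
else synonymous. Start-codon and stop-codon loss have no category of
their own and are reported as missense with a `note`
(`start_loss`/`stop_loss`). The up/downstream flank is 5 kb on either
side of the gene span. When a variant overlaps several gene models,
`annotate_variants()` can reduce to the most severe annotation
(nonsense > splice_site > missense > synonymous > UTR > intron > flank);
a gene-body feature always beats a neighbouring gene's flank because the
severity ranking places flanks last. Non-coding models (no CDS) report
exonic variants as `utr3` with a `non_coding_transcript` note — the
category list has no non-coding-exon class, and "untranslated" is at
least literally true.

Correctness is anchored by two property tests: annotating a minus-strand
gene must equal annotating the reverse-complemented locus as plus strand,
and a variant is synonymous iff independently translating the whole
mutated CDS (Biostrings) leaves the protein unchanged.

## Population statistics

* `spectrum_table()` strand-collapses substitutions into five classes;
  complementing every mutation leaves the table invariant by
  construction.
* `mutation_density(n, bp, plants)` returns `bp/(n/plants)/1000` — kb of
  covered sequence per mutation per plant. Zero mutations yield an
  explicit sentinel, not an error. The covered-bp denominator is the
  caller's choice (the function exposes all three quantities) because
  published densities are ambiguous about on-target vs total covered
  sequence.
* `plants_to_screen(L_kb, density)` = density/L: at 1/154 kb a 2 kb gene
  needs ≈ 77 plants per expected mutation.
* `exome_filter()` applies the multi-sample hard-filter cascade in fixed
  order: drop indels → per-sample depth < 4 set missing → drop sites
  informative in < 15 of 20 samples → drop QD < 2.0 → drop FS > 20.0
  **and** SOR > 4.0 → drop positions carried by more than one plant.
  "Sufficient reads in at least 15 of 20 samples" is read as ≥ 4 reads in
  ≥ 15 samples (any other reading leaves "sufficient" undefined), and
  "one SNP per position" as *one carrier plant* per position — shared
  positions are treated as probable pre-existing polymorphism or
  outcrossing, which is the filter's purpose. QD/FS/SOR are consumed from
  VCF INFO, never recomputed; sites missing an annotation pass that
  predicate with a warning rather than silently failing half the cascade.
  The cascade is order-invariant in its input rows.
* `het_fraction_filter()` drops heterozygous individual-library calls
  with alternate fraction < 0.40; homozygous calls are untouched.
* `design_probes()` steps `round(probe_len/tiling)` bp (80/3 → 27) and
  end-anchors a final probe when the last regular probe undershoots the
  target; rounding and end-anchoring are this package's convention (only
  density and size are standard). Published probe totals also reflect
  multi-mapping removal against a genome, which is out of scope, so no
  count equality is asserted anywhere.

## Coordinates and formats

All internal coordinates are 1-based and inclusive, the native convention
of VCF, GFF3 and R/Bioconductor — using one convention everywhere removes
the boundary conversions where off-by-one errors breed. FASTA I/O is
Biostrings, VCF parsing is vcfR (multi-allelic records are decomposed to
biallelic on read, since the pooled pipeline reasons per alternate
allele), GFF3 import is rtracklayer. VCF writing is a small formatter for
the fields this package uses (`GT:DP:AD` per sample, QD/FS/SOR INFO);
write-then-read round trips are tested losslessly. Sample sheets mapping
libraries to (block, axis, index) are TSV — pools are a wet-lab construct
orthogonal to the variant format, so they do not live in VCF headers.

## Problem sizes in the test and acceptance suites

The suites simulate at sizes chosen to make sampling bands tight while
keeping runs quick on a laptop: density recovery uses 20 plants over
50 Mb (≈ 6 500 mutations, 3 SE ≈ ±6 kb around 154), spectrum recovery
17 818 draws (3 binomial SE ≈ ±0.9 % around 79.4 %), and the end-to-end
recovery property one 16 × 16 block over 40 kb of targets at depth 10⁴
(≥ 200 single-carrier variants, sensitivity and zygosity accuracy
≥ 0.95). Exhaustive oracle comparisons cover every hit pattern on grids
up to 4 × 4.

## Known limitations

Only 2D (row × column) pooling is supported — no 3D or replicated
designs, and no probabilistic decoding of ambiguous patterns. Detection
is purely threshold-based (no per-site error model or base-quality use).
Annotation handles one transcript per gene and SNVs only. The simulator
is site-independent: it will not reproduce linked mutations or local
mutation clustering. These boundaries are deliberate: the package models the
screen's decision rules, not the sequencing instrument.
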