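---
title: "Quantifying a satellitome from low-coverage reads: models and methods"
author: "satkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying a satellitome from low-coverage reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satkit)
```

## The problem

Satellite DNA (satDNA) consists of long tandem arrays of a repeated
monomer, concentrated in heterochromatin. The full complement of satDNA
families in a genome — its *satellitome* — is routinely characterized
from cheap low-coverage short-read surveys rather than from assemblies,
because assemblers collapse exactly the long homogeneous arrays that
carry most of the satellite content. The standard workflow aligns a
random read sample against a library of per-family consensus monomers
and summarizes each family by

* **genome proportion**: percent of sampled bp assigned to the family
  ("read percentages");
* a **divergence landscape**: abundance binned by the Kimura
  2-parameter (K2P) distance of each read from the consensus;
* **DivPeak**: the divergence bin where the landscape is maximal, a
  proxy for time since the family's last expansion/homogenization;
* **RSP** (relative peak size): the fraction of the family's abundance
  within ±2 bins of DivPeak, a proxy for homogenization;
* **TSI** (tandem structure index): the fraction of family-aligned
  reads aligned over ≥ 89% of their length, a proxy for array
  clusterization (long arrays → most reads are pure satellite).

`satkit` implements this workflow end to end — read simulation,
monomer-period detection, seeded local alignment, the statistics above,
and cross-sample comparison (log2 abundance ratios, presence calls,
Spearman rank correlation, exact Wilcoxon signed-rank test) — so that
every statistic can be validated by parameter recovery on synthetic
genomes with known ground truth.

## Alignment model

Reads are aligned not to the monomer but to a **dimer** (two
concatenated monomer copies), or for monomers under 100 bp to the
smallest whole-number concatemer of at least 200 bp. A read starting
anywhere in an array then always has a contiguous image in the
reference; the 100 bp cutoff makes the two conventions (dimers
vs ~200 bp concatenations) a single deterministic rule.

`maskSample()` is seed-and-extend: a read becomes a candidate for a
family when it shares an exact 12-mer with either strand of the
family's reference (`Biostrings` PDict machinery); candidates are
aligned by Smith–Waterman local alignment with match +1, mismatch −1,
and affine gaps costing 4 for the first gap base and 1 for each
additional base. Records with score < 18 or fewer than 30 aligned
columns are dropped; overlapping hits on one read are resolved to the
highest-scoring family (ties: lower family rank), so abundances add up.
All of these thresholds are exposed as arguments, and all defaults are
deliberate choices: 12-mer seeds keep the all-pairs alignment
desk-scale; score 18 rejects essentially all background (the suite
checks a false-positive rate below 0.1% of reads) while retaining
satellite reads up to ~25% divergence.

Each record's divergence is the K2P distance
$K = -\tfrac12\ln\!\big[(1-2P-Q)\sqrt{1-2Q}\big]$, with $P$ and $Q$ the
transition and transversion proportions over ungapped, unambiguous
aligned columns. Gap and ambiguity columns count in neither numerator
nor denominator. Saturated alignments (log-domain violations) get `NA`
divergence and are excluded from landscapes; no CpG adjustment is
applied. Landscapes use 1-percentage-point bins with floor binning —
the convention of repeat-landscape tooling — and the ±2% RSP window is
read as ±2 integer bins (a 5-bin window truncated at bin 0); only this
integer reading can yield an RSP of exactly 1.00 for a zero-divergence
family, which the published reference table contains.

For assemblies, `maskAssembly()` cuts contigs into 1000 bp windows
overlapping by 150 bp, masks windows like reads, then re-masks the
unaligned flanks of hit windows iteratively (windows are much longer
than a dimer, so a single best local hit per window would undercount
long arrays) and finally deduplicates hits per family by genomic
coordinate, greedily by score. The collapsed-array underestimation seen
when assemblies replace long arrays with a token monomer or two is
reproduced in the test suite with a constructed collapsed genome.

## The synthetic-data generator

`simSpec()`/`buildGenome()` emulate the data a low-coverage mammalian
survey provides. The defaults are the package's study conditions: a
2 Mb genome, i.i.d. background at 59% A+T, single-end 150 bp reads at
2× coverage. Each family is defined by a consensus monomer, a target
genome proportion, an expected K2P divergence, a transition/transversion
rate ratio κ (default 2, a typical mammalian value), a number of arrays,
and a gamma-distributed array-length model with a chosen CV (minimum one
monomer per array) controlling clusterization for TSI experiments.

The mutation model inverts the estimator: for divergence $d$ and rate
ratio $\kappa = \alpha/\beta$, with $s = \beta t$ solved from
$d = 2s(\kappa + 2)$, each site is substituted with transition
probability $P = \tfrac14(1 - 2e^{-4s(\kappa+1)} + e^{-8s})$ and total
transversion probability $Q = \tfrac12(1 - e^{-8s})$, so the K2P
estimate between a copy and its consensus has expectation $d$. Copies
are mutated independently from the consensus (a star phylogeny): the
generator models homogenization level only through $d$ itself, not
through a duplication history. Arrays are placed in random order with at
least two read lengths of background between them and from the genome
ends, so no read can span two arrays. Indels (off by default) and a flat
sequencing substitution error (also off) are available but play no role
in the shipped scenarios, since every statistic here is driven by repeat
divergence rather than sequencing error. Reads are single-end with
uniform starts and equiprobable strands; `N_reads = round(coverage ×
genome_length / read_length)`. Pairing would change none of the
computed statistics, which is why the generator does not model it.

Every generated genome comes with a `TruthTable`: per-family inserted
bp and proportion, the realized mean per-copy K2P divergence, and the
exact array intervals — the ground truth against which recovery is
judged. What the generator does *not* emulate: real Illumina
error/quality profiles, transposable elements and other non-satellite
repeats, CpG hypermutability, library-preparation bias, and any
non-star homogenization history. Passing recovery tests therefore show
that the estimators are correct for data matching the model's
assumptions, not that real genomes satisfy those assumptions.

## Period detection and consensus building

The discovery step of real satellitome studies (graph clustering of
reads, then visual dotplot inspection of cluster contigs) is replaced
by a quantitative periodicity detector. `detectPeriod()` computes, for
every candidate period $p$, the mean base identity between the contig
and itself shifted by $p$ — the diagonal signal of a dotplot — and
reports the *fundamental* period: the smallest $p$ within 0.01 identity
of the maximum, which resolves the multiple-of-period ambiguity all
dotplots share. Below 0.6 identity no tandem structure is called; the
threshold is chosen so the noiseless case is exact and 10%-diverged
arrays are still comfortably above it. Monomer windows are cut from
phase 0 (the phase maximizing the number of complete monomers),
stacked, and reduced by `majorityConsensus()` (per-column majority,
gap-majority columns dropped, ties broken in the fixed order
A < C < G < T). Because the start of a monomer in an array is
arbitrary, family comparison uses `canonicalRotation()` — the
lexicographically smallest rotation. Families are then named
`<tag>Sat<rank>-<length>` by decreasing measured abundance, ties broken
by longer monomer first, then monomer sequence.

## Comparative layer

Cross-sample comparison assumes all samples were masked with the same
library; abundances are already percentages of each sample's own
sampled bp, so samples of different depth compare directly.
`log2Ratio()` is only defined when a family is present on both sides;
presence itself has no standard definition in the field, so
`presenceCall()` uses deliberate, permissive floors (≥ 1e-4% abundance
and ≥ 10 supporting reads), both exposed and reported. Changes are
called at |log2 ratio| > 0.6 with strict inequalities.
`spearmanRho()` is the Pearson correlation of average ranks with a
two-sided t-approximation p-value (adequate at the n ≈ 17 of a
satellitome table); `wilcoxonSignedRankExact()` enumerates the exact
signed-rank distribution by a generating-function convolution over
doubled ranks, which handles tied |differences| via average ranks —
something classical exact tables cannot — and matches full $2^n$
enumeration in the tests. Its two-sided p-value is the symmetric-tail
probability $P(|W - \bar W| \ge |w_{obs} - \bar W|)$; with all
differences zero the p-value is 1 by convention.

## Validation scenarios and their statistical limits

Four canonical scenarios (`scenarioRecovery()`, `scenarioLadder()`,
`scenarioTsi()`, `scenarioComparative()`) fix the data-generating
processes used by the test suite and the acceptance script. All run on
2 Mb genomes at 2× coverage — sizes chosen so a full validation pass
runs in minutes on one CPU while keeping the largest families' sampling
error in the low percent range.

One limit deserves honesty: DivPeak is the argmax of a 1-point-binned
histogram. For a family occupying only 0.3% of a 2 Mb genome at 2×
coverage (~80 aligned reads), the per-read K2P estimate has a standard
deviation near 3 points at 12% divergence, and the star-phylogeny copy
divergences themselves scatter with sd ≈ 2.8 points across the ~35
copies present, so the argmax bin fluctuates by several bins between
seeds. Recovering DivPeak to ±1 bin is therefore reliable for abundant
or young families but *not* for rare, diverged ones at this problem
size; the corresponding acceptance check documents this, and the
recovery test for the 12%-divergence, 0.3% family can fail at a given
seed for exactly this reason. Mean K2P divergence (bp-weighted) is the
stabler degeneration summary at small read counts. A second,
deterministic effect is worth noting: local alignment preferentially
retains the better-matching subsegments of a read, which biases
per-read divergence down by roughly half a point to a point at high
divergence — an artifact shared by all local-alignment-based repeat
annotation.

## Worked example

```{r example, eval = FALSE}
spec <- scenarioRecovery(seed = 1)
sim <- buildGenome(spec)
reads <- shearReads(sim$genome, 150, 2, seed = 2)
lib <- nameFamilies(vapply(spec@families, slot, character(1), "monomer"),
                    c(0.01, 0.005, 0.003, 0.001), "Sim")
mask <- maskSample(reads, lib)
satellitomeTable(mask, lib)
```

The packaged reference table (`taquTable1()`) ships the published
per-family summary of the *Talpa aquitania* satellitome — 17 entries:
15 families with one family split into its two monomer-length variants,
plus the telomeric (TTAGGG)$_{50}$ repeat — and is the fixture against
which `summarizeTable()` and `spearmanRho()` are checked (mean monomer
length 289.24 bp, median 71.00; mean A+T 50.43%; mean K2P divergence
13.07%; mean TSI 0.53; mean DivPeak 13.06; mean RSP 0.48; total
satellitome 1.24%; Spearman ρ(DivPeak, RSP) ≈ −0.74 on the rounded
published values).

## Known limitations

* Equivalence with any specific repeat-annotation tool's output is not
  claimed: scoring, seeding and overlap resolution are this package's
  own documented choices.
* Graph-based read clustering (the discovery step of real surveys) is
  out of scope; `detectPeriod()` operates on already-assembled
  repetitive contigs.
* The lepto/meso/platykurtic landscape labels are qualitative in the
  field; `classifyLandscape()` operationalizes them with configurable
  thresholds (RSP ≥ 0.8 and DivPeak ≤ 5; RSP ≤ 0.3 and DivPeak ≥ 15)
  and should be read as a convenience, not a standard.
* The exact Wilcoxon test enumerates up to n = 25 non-zero pairs;
  beyond that it refuses rather than silently approximating.
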