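---
title: "Reconstructing and authenticating ancient mitochondrial genomes"
author: "ancientMito"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing and authenticating ancient mitochondrial genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ancientMito)
```

## Scope

`ancientMito` implements the computational workflow used in ancient-DNA
studies of mitochondrial genomes from late Pleistocene faunal remains:
simulation of damaged short-fragment libraries, paired-end merging,
iterative reference-guided assembly with damage-tolerant mapping, terminal
misincorporation profiling with an authenticity verdict, phylogenetic
placement under GTR+G+I likelihood and Fitch parsimony with bootstrap
supports, cytochrome-b mismatch counting, and collagen stable-isotope
quality control with a niche-overlap statistic. Everything downstream of a
sequencer is covered; wet-lab steps (extraction, library preparation,
hybridization capture) and radiocarbon calibration are out of scope.

## The damage model

Post-mortem hydrolytic deamination converts cytosine to uracil, read as
thymine. The lesion concentrates in single-stranded overhangs at fragment
ends, so ancient libraries show C→T substitutions rising sharply toward the
read 5' end and — in double-strand library protocols — the complementary
G→A signal at the 3' end.

`DamageModel` parameterizes the standard overhang construction:

* `overhangDecay` (q): position *p* (1-based from a fragment end) is
  single-stranded with probability *q^p*, a geometric overhang-length
  model that produces the familiar monotone decay of misincorporation
  curves.
* `deltaSS`: deamination probability for a cytosine inside an overhang.
* `deltaDS`: residual deamination in the double-stranded interior
  (typically one to two orders of magnitude smaller).
* `bothStrands`: with a double-strand protocol both strands of each
  molecule enter the library. A sequenced read is then in the sense of the
  deaminated template with probability 1/2 (showing 5' C→T) and in the
  complementary sense otherwise (showing the same lesions as 3' G→A).

This bookkeeping gives the closed-form pooled terminal frequency

> E[C→T at 5' position p] = ½ · (q^p · deltaSS + (1 − q^p) · deltaDS),

exposed as `expectedTerminalFrequency()`. The ½ is the double-strand
protocol's theoretical 50% ceiling: even complete deamination of every
overhang cytosine (q = 1, deltaSS = 1) yields 50% observed terminal C→T,
because half the reads are complements carrying the signal at the other
end. A single-strand protocol (`bothStrands = FALSE`) has no such factor
and saturates at 100%, with C→T at both ends. The simulator
(`applyDamage`) draws the read sense per fragment and applies exactly this
law, recording every altered position as ground truth; the profiler's
estimator is therefore checked against an independent analytic oracle, not
against itself.

## Synthetic libraries

`simulateReference` draws an i.i.d. circular genome at a chosen GC
fraction (defaults emulate a ~16.5 kb mitogenome at GC 0.4).
`simulateFragments` places fragments uniformly, allowing wrap-around at
the circular origin. Fragment lengths are `minLength` plus a negative
binomial with mean `meanLength − minLength` and size `dispersion`: the
study conditions call for mean read lengths near 60 bp (low-input
specimens) and 85 bp, and the negative binomial reproduces those means
exactly while giving a realistic right-skewed spread; no published length
distribution was available, so the family is a package choice, documented
here once. `emitFastqPairs` writes 2×`readLength` paired FASTQ with
constant Q37 qualities (no quality model is specified for the emulated
instrument; a constant keeps merge tie-breaking transparent) and recycles
a standard adapter into read-through tails. `simulateIsotopeTable`
generates collagen isotope records with the instrument's analytic noise
(±0.1‰ δ13C, ±0.2‰ δ15N) and a configurable fraction of C/N failures.

## Merging and filtering

Mates are merged when the best placement of mate 1 against the
reverse-complemented mate 2 overlaps by at least `minOverlap = 11` bases;
merged reads shorter than `minLength = 30` are discarded, as are unmerged
pairs. The scan scores every candidate fragment length as matches minus
mismatches over the overlap (N counts as mismatch), breaking ties toward
the longer overlap and then the shorter fragment, which collapses
read-through pairs onto the fragment and removes adapter implicitly. The
overlap mismatch tolerance (`maxMismatchFraction = 0.1`) is a package
default — terminal deamination produces real mismatches between mates'
overlapping copies — and is not a published constant. In the overlap the
higher-quality base wins and keeps its quality; ties favour mate 1.

## Iterative assembly

`mapReads` is a k-mer-seeded (k = 12), banded (half-width 8) affine
aligner against the doubled circular reference: match +1, mismatch −1, gap
open −2, gap extend −1. With `damageAware = TRUE` the penalty of a
C(ref)→T(read) mismatch *p* bases from the aligned 5' end — and of
G→A from the 3' end — is multiplied by (1 − 0.5^p): a terminal
deamination mismatch costs −0.5 instead of −1, and the discount fades
geometrically into the read so interior mismatches pay full price. The
matrix values are package defaults in the spirit of damage-tolerant
iterative assemblers, whose exact matrices are not published alongside the
workflow. Alignments scoring below half the read length are unmapped,
which keeps contaminant and blank-library reads out of the pileup.

One subtlety is worth recording: when a read carries deamination at its
two outermost bases, a placement with a short terminal deletion can
occasionally outscore the true placement (the discounted mismatches cost
more than one gap). This affects well under 0.1% of reads in the default
conditions and nudges the profiled position-1 frequency down by roughly
0.1–0.3 percentage points relative to ground truth — visible only because
the simulator provides truth, and shared by any score-maximizing mapper
with damage discounts.

Duplicates collapse on identical (start, end, strand) — both endpoints,
matching the "unique mapped fragments" convention — keeping the copy with
the highest summed base quality. `callConsensus` emits the majority base
where unique coverage is at least `minCoverage = 3` and the majority
fraction (default 0.5) is met; ties and sub-threshold positions are N.
`iterateAssembly` repeats map → dedup → consensus, substituting the
previous reference base at N positions *for mapping only*, until the
consensus is byte-identical between rounds (cap 10). Convergence from a
reference several percent divergent is typically reached in two rounds;
the final consensus keeps N where coverage is insufficient. Coincidental
clusters of divergence that mimic a tandem shift can trap any
reference-guided assembler in a locally stable gapped interpretation; the
test suite uses isolated substitutions, and real cross-species references
behave like the scattered case almost everywhere.

## Authentication

`profileDamage` tabulates all twelve substitution types at the first K
(default 25) positions from each read end, in read orientation,
conditioning on the aligned reference base: frequency(X→Y at p) =
count(X→Y at p) / count(reference X at p). The conditional convention is
deliberate — it is the definition under which the double-strand protocol's
50% ceiling is exact; a "fraction of all reads" definition would scale
with base composition. Consensus-N columns are excluded; zero-opportunity
positions report NA rather than 0. `authenticate` applies the standard
conjunctive rule: a library is authentic ancient DNA only if both the
5'-terminal C→T and 3'-terminal G→A frequencies reach 20% (inclusive).
Undefined terminal frequencies yield an indeterminate verdict rather than
a pass or fail.

## Phylogenetic placement

`maskAlignment` implements complete deletion: columns in excluded regions
(e.g. the hypervariable D-loop, which is conventionally removed before
deep cervid phylogenetics), columns containing any gap or ambiguity, and
columns where any ancient taxon's coverage is below 3-fold are dropped
from all computations.

The likelihood engine is Felsenstein pruning under GTR+G+I. Gamma rate
heterogeneity uses equal-probability categories with mean-of-quantile
rates (default 5 categories, shape α = 0.3366 — the value fitted for
cervid mitogenome alignments); with a proportion of invariant sites
`pInvariant`, variable-category rates are rescaled by 1/(1 − pInvariant)
so the expected rate is exactly 1, and the site likelihood is
pInv·I(site constant)·π(base) + (1 − pInv)·mean over categories. GTR
exchangeabilities and base frequencies are user-supplied or left at
defaults, since only the model family and α are fixed by convention.
Detailed balance, stochasticity of P(t), rate-mean normalization, pulley
invariance and agreement with both a brute-force state-summation oracle
and an independent likelihood implementation are asserted in the tests.

Parsimony is Fitch's bitwise algorithm; per-branch step counts come from a
unit-cost Sankoff pass whose top-down assignment keeps the parent state
whenever it is within one step of optimal and otherwise takes the
lowest-index base — a deterministic most-parsimonious reconstruction whose
branch sums equal the Fitch score.

`searchTree` starts from neighbour joining (log-det distances for ML — a
transform consistent under general time-reversible evolution — and
p-distances for MP) and hill-climbs over nearest-neighbour interchanges,
accepting the first improving neighbour in a fixed order until none
improves. ML branch lengths are optimized by cycled single-branch Brent
steps (interval [1e-8, 5], tolerance 1e-6) until the log-likelihood gains
less than 1e-4 per cycle; MP edge lengths are the per-branch step counts.
`bootstrapTree` resamples columns with replacement (default 1000
replicates; tests and examples use fewer and say so), reruns the search,
and reports bipartition support percentages on the point-estimate tree,
which `rootWithOutgroup` roots on an outgroup's pendant edge.
`countMismatches` counts pairwise differences only where both bases are
unambiguous, reporting N/gap columns as unresolved — the convention under
which a partially reconstructed cytochrome b with a handful of unresolved
bases is compared against published sequences.

## Stable isotopes

`qcFilter` derives the atomic C/N ratio from elemental composition
((%C/12.011)/(%N/14.007)) and retains records inside the inclusive
2.9–3.6 collagen-reliability window; records lacking composition are
flagged unassessable rather than silently dropped. `overlapScore` makes
the visual "falls inside the cluster" comparison computable: overlap is
the area of the intersection of the two groups' convex hulls in
(δ13C, δ15N) space divided by the area of their union
(Sutherland–Hodgman clipping, exact for convex inputs), with query
specimens classified inside/outside each hull. Collinear degenerate hulls
fall back to 1-D segment overlap and are flagged. The metric is an
analytic choice of this package — the comparison it formalizes is
qualitative in the field — and is symmetric and invariant under
translation and rotation of the isotope plane.

## Orchestration and reproducibility

`runPipeline` chains simulate → emit → merge → assemble → authenticate
(→ isotopes) under a single seed, fanning out deterministic per-stage
seeds, persisting every intermediate (FASTQ/FASTA/TSV/JSON) under the run
directory and serializing the effective configuration into the report, so
every reported number is recomputable from the persisted inputs. All
defaults equal the canonical constants (11 bp overlap, 30 bp length, 3-fold
coverage, 20% threshold, α = 0.3366 with 5 categories, 1000 bootstrap
replicates, C/N 2.9–3.6). Stage failures are recorded in the report and
later stages are skipped rather than run on malformed input.

## Problem sizes and what the tests show

The suite exercises: oracle equivalence for merging, mapping, parsimony
and pruning on small instances (reads ≤ 50 bp, references ≤ 200 bp, 4–6
taxa); exact reference recovery for a zero-damage, zero-error library
(4 kb genome, 30-fold coverage); topology recovery for an 8-taxon tree
from 10 kb simulated alignments under both criteria; damage-parameter
recovery within two standard errors at 100,000 reads; and the 50%
double-strand ceiling. These sizes make the full suite run in a few
minutes while leaving the estimators' standard errors small relative to
the tolerances.

Passing them shows that the implementation computes what the models say —
it does not show that the models capture every property of real ancient
libraries. The simulator draws i.i.d. genomes without repeats or base
composition structure, constant qualities, uniform fragment placement, and
damage that follows the overhang law exactly; real data add reference
bias, indel error, fragmentation hotspots, contamination mixtures and
library artefacts that are deliberately outside the generator.

## Known limitations

* The mapper is a seeded banded aligner adequate for mitogenome-scale
  references; it is not a general-purpose short-read aligner and does not
  emit SAM/BAM.
* No likelihood-based damage-model fitting or quality rescaling: the
  profiler estimates frequencies and applies the threshold rule only.
* ML model parameters (exchangeabilities, base frequencies, pInvariant)
  are not optimized; only branch lengths are.
* NNI hill climbing can stop in local optima on hard landscapes; the
  bootstrap reruns the same search and inherits the limitation.
* Convex-hull overlap is sensitive to outliers by construction; with
  fewer than three records per group no hull exists and an error is
  raised rather than a guess.
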