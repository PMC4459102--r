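# ancientMito

Tools for reconstructing, authenticating and placing ancient mitochondrial
genomes from short, damaged sequencing reads — the computational half of a
palaeogenetic mitogenome study, from raw paired-end FASTQ to an
authenticated consensus, a phylogenetic position and collagen-isotope
quality control. It is aimed at researchers analysing (or simulating)
hybridization-capture mtDNA data from Pleistocene faunal or hominin
remains.

## What it computes

**Damage model.** Post-mortem cytosine deamination in single-stranded
overhangs produces C→T substitutions at read 5' ends and, under a
double-strand library protocol, the complementary G→A signal at 3' ends.
With overhang decay *q*, single-stranded rate δ<sub>ss</sub> and
double-stranded rate δ<sub>ds</sub>, the pooled terminal substitution
frequency at position *p* is

E[C→T at p] = ½ (q^p δ_ss + (1 − q^p) δ_ds)

— the ½ because both strands of each molecule are sequenced, which caps
terminal damage at 50%. The package both *simulates* this process (with
recorded ground truth) and *estimates* it from alignments, conditioning
each frequency on the aligned reference base. A library is authenticated
as ancient when both terminal frequencies reach 20%.

**Processing.** Mate pairs are merged on a best overlap of ≥ 11 bp,
length-filtered at ≥ 30 bp, mapped with a damage-tolerant banded aligner
(terminal C→T/G→A mismatch penalties discounted by 1 − 0.5^p),
deduplicated on identical (start, end, strand), and assembled by iterating
map → consensus until convergence; consensus bases require ≥ 3-fold unique
coverage, otherwise N.

**Placement.** Alignment masking (D-loop-style region exclusion, complete
deletion of gap columns, 3-fold coverage masks), GTR+G+I log-likelihood by
Felsenstein pruning (5 gamma categories, mean-of-quantile rates, shape
default 0.3366), Fitch parsimony with exact per-branch step counts, NJ +
NNI tree search under either criterion, bootstrap bipartition supports,
outgroup rooting, and cytochrome-b style pairwise mismatch counting where
N/gap columns count as unresolved, not as differences.

**Isotopes.** Collagen records pass QC when the atomic C/N ratio
(%C/12.011)/(%N/14.007) lies in 2.9–3.6 (inclusive); niche overlap between
two taxa in (δ13C, δ15N) space is the convex-hull
intersection-over-union, with query specimens classified inside/outside
each hull.

## Worked example

Simulate an ancient-like double-strand library whose closed-form terminal
C→T expectation is 27%, process it end to end, and authenticate:

```r
library(ancientMito)

ref <- simulateReference(16500, gc = 0.4, seed = 1, id = "mt_sim")
dm  <- DamageModel(overhangDecay = 0.6, deltaSS = 0.9, deltaDS = 0.01,
                   bothStrands = TRUE)
dm
#> DamageModel: overhang decay 0.6, deltaSS 0.9, deltaDS 0.01, double-strand protocol
#>   expected 5'-terminal C->T frequency: 27.2%

sim <- simulateReadSet(ref, FragmentationModel(meanLength = 60,
                                               coverageTarget = 30),
                       dm, seed = 2, n = 20000)
f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
emitFastqPairs(sim$seq, readLength = 100, out1 = f1, out2 = f2, seed = 3)
merged <- mergeFastq(f1, f2, tempfile(fileext = ".fastq"))

asm <- iterateAssembly(merged$retained$seq, ref,
                       quals = merged$retained$qual,
                       ids = merged$retained$id)
asm
#> AssemblyResult: 16500 bp consensus, 19865 unique fragments, 2 iteration(s)
#>   100.00% of positions at >= threshold coverage, mean unique coverage 72.4x

authenticate(profileDamage(asm@alignments, consensusSeq(asm)))
#> AuthenticationVerdict: authentic ancient DNA (5' C->T 27.6%, 3' G->A 26.5%, threshold 20%)
```

The estimated terminal frequencies (27.6% / 26.5%) sit within sampling
error of the generative 27.2% expectation, and the verdict clears the 20%
rule on both ends. An undamaged (blank-like) library run through the same
pipeline profiles at ~0% and is reported as not authentic. `runPipeline()`
wraps the same chain under one seed and writes every intermediate plus a
JSON report; `searchTree()`, `bootstrapTree()` and `overlapScore()` cover
the placement and isotope analyses.

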