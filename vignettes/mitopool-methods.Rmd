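---
title: "Tag-free multiplex mitogenome sequencing: methods and design notes"
author: "mitopool"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tag-free multiplex mitogenome sequencing: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitopool)
```

## The problem

Metazoan mitochondrial genomes (~14–20 kb, circular, 13 protein-coding
genes, 2 rRNAs, 22 tRNAs and a control region) can be sequenced in
multiplex *without* synthetic barcodes: if the pooled specimens are
divergent enough all along their mitogenomes, each genome's reads
assemble into distinct contigs, and the contigs can be attributed to
their specimens afterwards by comparing them with reference barcode
markers (COI, 12S, 16S, CYTB) — the sequences themselves act as tags.
`mitopool` implements the desk-side half of that workflow:

1. **Screening** — decide which specimens may share an untagged run;
2. **Planning** — pool construction and per-run capacity/cost;
3. **In-silico validation** — read simulation from pooled circular
   genomes, a baseline assembler, contig-to-reference demultiplexing
   and contig-to-truth evaluation.

## Screening: p-distances, the Folmer proxy and sliding windows

The elementary statistic is the **p-distance**: the fraction of
mismatching sites among comparable alignment columns. We use *pairwise
deletion* (columns with a gap or N in either row are excluded) so that
local indels do not contaminate neighbouring windows; `pDistance()`
returns the number of comparable columns alongside the estimate.
Model-corrected distances (K2P and relatives) are deliberately out of
scope: screening targets closely related species where mutational
saturation is negligible, and raw mismatch fractions are what the
thresholds below were calibrated on.

Two screening instruments are provided:

* `folmerProxy()` extracts the **Folmer fragment** — positions 50–700 of
  the COI gene, read 1-based inclusive, i.e. the conventional ~650 bp
  animal barcode (651 bp for a full-length COI) — aligns the two
  fragments and returns their p-distance. This is the cheap proxy
  available for tens of thousands of species.
* `slidingProfile()` computes p-distances in windows of 150 or 450
  alignment columns, stepped by 15 or 45 (one tenth of the window), the
  two settings matching short-read (Illumina/Ion Torrent) and long-read
  (454) screening. The window count is `floor((L - w)/s) + 1`.

A window where fewer than half the columns are comparable (default
`minComparableFrac = 0.5`) is flagged **low-information** and carries
`NA` rather than a p-distance. This matters: when one sequence carries a
long deletion, a naive profile reports 0% divergence across the span —
an artifact of the visualisation, not a real identical region — and
would veto perfectly poolable pairs. `minWindowDivergence()` skips
flagged windows.

Pairwise alignments are produced by `alignAnchored()`: unique shared
15-mers are chained (longest collinear subsequence), and the
inter-anchor segments are filled with affine-gap Needleman–Wunsch
(match +1, mismatch −1, gap open −4, extend −1 per base; a gap of
length *L* costs 4 + *L*). The parameters are recorded in the alignment
object. Pairs with fewer than three collinear anchors are refused with
an instruction to supply an external alignment — at that divergence the
screening answer is "do not pool" anyway. On sequences up to 2 kb the
anchored aligner reproduces the score-optimal global alignment (tested
against an independent full dynamic-programming implementation).

## Pooling policy and pool construction

The empirical pooling rule: pairs whose Folmer COI divergence exceeds
**15%** essentially never show a single 450 bp window below **5%**
divergence anywhere along the mitogenome. `compatPolicy()` exposes both
thresholds (`coiThreshold = 0.15`, `windowThreshold = 0.05`) and three
modes — proxy only, windows only, or windows preferred with proxy
fallback. Pairs lacking the required evidence are conservatively
**incompatible** and flagged `"insufficient data"`: a specimen without
reference data should be sequenced separately rather than risked in a
pool.

`maxPool()` finds a maximum clique of the compatibility graph — exact
branch-and-bound up to 25 specimens, greedy-plus-swap local search with
a fixed seed above (the bound is reported); ties break towards the
lexicographically smallest member list so results are reproducible.
`partitionPools()` colours the incompatibility graph with DSATUR and
reports the largest incompatible clique as a lower bound on the number
of runs. On random 8-node instances the heuristic matches the exact
chromatic number on ≥90% of cases and never exceeds it by more than one
colour (tested against a backtracking oracle).

## Run capacity and cost

With a library whose mitochondrial fraction is `mitoFraction` (default
0.5, a realistic size-selection enrichment) and equimolar pooling,

```
genomes per run = throughput × mitoFraction / (genomeLength × coverage)
```

with `genomeLength = 17,000` bp by default. `runCapacity()` rounds the
genome count half-up and divides the run cost by the *unrounded*
quotient, rounding to 2 decimals — the unique rounding rule that
reproduces every published capacity/cost cell for the bench-top
platforms tabulated in `sequencerSpecs()` (e.g. 35 Mb at 20× → 51.47 →
51 genomes, \$1100/51.47 → \$21.37 per genome).

```{r capacity}
capacityTable()[, c("platform", "genomes_20x", "genomes_50x",
                    "genomes_100x", "cost_per_genome")]
```

## Read simulation

`simulatePool()` uses a two-level error parameterisation:

* **Haplotype mutations**, once per genome per run
  (`mutationRate = 0.001` per site): 9/10 substitutions, 1/10 indels
  with geometric length (extension probability `indelExt = 0.3`, mean
  1/(1−0.3) ≈ 1.43, capped at 10 bp). This models the true specimen
  haplotype differing from its reference.
* **Read errors**: independent per-base substitutions at
  `errorRate = 0.02`.

Reads start uniformly on the circle (origin-spanning reads carry
`wrapped = TRUE` in the truth table) with uniform strand; read length is
fixed rather than drawn from a distribution, which keeps every oracle
exact. Exactly `ceil(coverage × length / readLength)` genome-derived
reads are drawn per genome, so the realised genome coverage equals its
nominal value; contamination is *additive* on top — `nRandom ~
Binomial(nGenome, p/(1−p))` uniform-random reads (`randomReadProb =
0.05`), giving the pool an expected 5% RANDOM fraction without eroding
genome coverage. Non-equimolar pooling is emulated by
`coverageLadder()`: genome *i* receives 10 + 2(*i*−1)×, so the 30th
genome of a pool sits at 68×.

Paired-end mode draws inserts from a truncated normal (500 ± 50 bp by
default; the insert size is a free parameter since no canonical value
exists) and emits mates adjacently with `/1`–`/2` suffixes. Every read
carries a truth record (origin genome or RANDOM, 0-based start, strand,
substitution count, wrap flag), and identical seeds give byte-identical
FASTQ and truth tables. `exactReads()` generates the error-free
uniform tiling variant, including origin-spanning reads.

An optional `homopolymerMode` acknowledges that some platforms
concentrate errors in homopolymer runs; it is off by default and not
used in any calibration, since no usable rates are published.

## Baseline assembly

`assembleReads()` is a deterministic de Bruijn **unitig** assembler
(canonical k-mers, default k = 31, implemented in C++): count k-mers,
prune nodes below `minCount`, emit maximal non-branching paths in a
fixed order. An isolated simple cycle — the signature of a cleanly
recovered circular genome — is emitted once with `circular = TRUE`,
its first and last (k−1)-mers coinciding. There is deliberately no
bubble popping or tip clipping: abundance pruning is the only error
control, which keeps the assembler's behaviour fully predictable for
evaluation purposes. Parity with production assemblers is a non-goal;
`readContigs()` adapts any external contig FASTA into the same
evaluation pipeline.

**Choosing `minCount`.** A true k-mer at coverage *c* with per-base
error rate *e* survives intact in a read with probability (1−e)^k, so
its expected abundance is `c (1−e)^31 ≈ 0.53 c` at e = 0.02. An
erroneous k-mer requires the same substitution at the same site in two
reads; at 40× the expected number of error k-mers reaching abundance
*m* falls steeply with *m*. We therefore use `minCount = 5` at 40×
(true abundance ≈ 21, error k-mers above 4 are rare) and `minCount = 3`
for the 10–28× ladder (true abundance ≈ 5 at 10×). The function default
stays at 2, the most permissive setting that removes singleton errors.

## Demultiplexing and evaluation

`assignContigs()` scores a contig against each reference taxon as the
largest fraction of a marker's canonical 15-mers contained in the
contig (strand-insensitive). A contig is *assigned* when its best score
reaches `minScore = 0.2` and is at least `margin = 2` times the
runner-up, *ambiguous* on ties, *unassigned* otherwise. At the pool
divergences the policy enforces (>15% COI), cross-taxon 15-mer sharing
is negligible ((1−0.24)^15 ≈ 0.016 per site), so false assignment is
effectively impossible while any contig covering ≥20% of a marker is
recovered. k = 15 balances specificity at mitogenome scale against
tolerance of the divergence between pool members; all three knobs are
exposed.

`mapContigsToTruth()` anchors contigs on the doubled truth genomes
(handling the origin wrap), infers strand and placement from anchor
diagonals, and computes base-level identity — an exact-substring
short-cut for error-free contigs, otherwise a global–local alignment of
the contig against its placed window. Contigs showing dense anchor
support over ≥500 bp to two or more genomes are flagged **chimeric**.
`overlapSummary()` reports, per truth genome, the best single-contig
overlap fraction and the circular union of covered bases, and counts
genomes whose best contig exceeds 33/50/66% — strictly greater, per
convention. The denominator is each genome's own length by default;
`fixed_16400` (the average mitogenome length of the published overlap
plots) is available for comparability. When a circular genome is
recovered as two contigs that tile it, the two are reported separately
— no merging — matching how assemblers that ignore circularity split
such genomes. `tetraProfile()` provides the 256-dimensional
tetranucleotide frequency vector occasionally used as an additional
composition cue (reported to structure mitogenome pools only weakly, so
no clustering is built on top of it).

## The synthetic family generator

All tests run on synthetic data from `makeFamily()`:

* `makeAncestor()` draws a uniform-random ~15.7 kb genome over an
  ordered layout of 13 PCGs (COI, 1,545 bp, first — the conventional
  linearisation point), 2 rRNAs, 22 tRNAs interleaved vertebrate-style
  and a control region; seeds yielding a duplicated 31-mer are rejected
  (repeat-free ancestors make assembler guarantees checkable).
* `evolve()` places an exact count of substitutions per region —
  `round(length × target × multiplier / weightedMean)` at distinct
  sites, each to a different base — so the realised divergence is a
  testable constant rather than an expectation. Class multipliers
  (PCG 1.0, rRNA 0.3, tRNA 0.5, CR 2.0) encode the qualitative
  conserved/variable mosaic of real mitogenomes: the rRNAs are the most
  conserved segment, the control region the fastest. The values are
  configuration, not biological estimates. Short indels (1–10 bp,
  geometric) are applied at `indelRate` (default 1e-4), never inside
  the Folmer window, so the COI proxy stays well-defined.
* `makeFamily()` evolves n taxa independently from one ancestor (a star
  phylogeny — sufficient for pool-design and demultiplexing tests, and
  it avoids tree I/O; a user-supplied tree is a possible extension).
  Because substitutions are placed at distinct sites per branch, a site
  hit on both branches still differs between two descendants with
  probability 2/3, so the expected pairwise divergence is
  `2t(1 − 2t/3)` for ancestor-divergence `t`; at the default
  target 0.12 all pairwise Folmer proxies comfortably clear the 15%
  pooling threshold.

What the generator does *not* emulate: codon structure, tRNA secondary
structure, gene-order rearrangements, compositional bias, heteroplasmy.
Passing tests therefore demonstrate the pipeline's mechanics and
calibration, not performance on real taxonomic data.

## A structural limit of the unitig baseline at k = 31

One negative result deserves emphasis. Consider the standard validation
pool: 10 genomes at ancestor-divergence 0.12 (pairwise ≈ 22% genome-wide,
every pairwise Folmer proxy above 15%, every informative 450 bp window
above 5%). Even then, the *conserved* regions retain long identical
stretches between pool members: at the rRNA pairwise divergence of
≈ 8%, the probability that a given 31-mer is identical between two
genomes is (1−0.08)^31 ≈ 0.08 per site, and even at 24% divergence
(protein-coding rate) it is ≈ 2 × 10⁻⁴ — roughly two shared 31-mers per
gene-sized region per pair. Every shared k-mer joins the two genomes'
paths in the pooled de Bruijn graph and terminates unitigs on both
sides. With 9 pool partners this yields hundreds of branch points per
genome, and the best unitig tops out at roughly 15–30% of the genome
length — although ~95–100% of each genome is covered by *some* contig,
assignment accuracy is 100% and no chimeras are formed (a unitig never
crosses a branch point, so it cannot splice genomes).

The consequence: a 5%-per-450 bp-window divergence floor does **not**
guarantee long contigs from a plain unitig assembler, because 5%
divergence still leaves 31-mer-scale identity with probability
0.95³¹ ≈ 0.2 per site. Read-overlap assemblers (the class used for the
original in-silico validation of this workflow, with 300–400 bp reads)
bridge isolated shared 31-mers because a full read spanning the shared
stretch still differs from the other genome elsewhere. The end-to-end
acceptance check of this package states the >50%-of-genome best-contig
targets for the record, and they fail for the unitig baseline under
exactly the conditions above — a property of the baseline assembler
class, not of the screening rule, the simulator or the demultiplexer,
all of which meet their targets. Users validating a real pooling design
should either run an overlap-based assembler on the simulated FASTQ
(via `writeFastq()` and `readContigs()`) or treat the unitig baseline's
covered-fraction, assignment-accuracy and chimera statistics — not its
contig lengths — as the decision-relevant outputs.

## Numerical and implementation choices

* Coordinates are 0-based half-open internally; annotation files (GFF3
  or the 5-column TSV) are 1-based inclusive on disk and converted on
  read.
* Canonical k-mers are 2-bit encoded (k ≤ 31 in 64 bits; k ≤ 15 in a
  31-bit integer code for the R-side index).
* FASTQ output writes a constant quality of
  `round(−10 log10(errorRate))` (cap 40), Phred+33.
* All stochastic components take explicit integer seeds and are
  byte-reproducible; heuristic components (clique search above 25
  nodes) carry fixed seeds and report bounds.
* Problem sizes used in the automated checks: 10-genome pools
  (~15.7 kb each) at 40× for the end-to-end runs, a 10–28× ladder over
  3 seeds for the coverage trend, 200 twelve-node and 100 eight-node
  instances for the combinatorial oracles, 1,000 random gapped pairs
  for the p-distance oracle, and 50 synthetic pairs for the
  window-variance comparison.

## Known limitations

* The anchored aligner is for *closely related* sequences; it refuses
  rather than guesses on divergent pairs.
* The unitig baseline's contig lengths degrade in conserved regions of
  pooled assemblies (see above); it has no tip/bubble resolution.
* Chimera detection for secondary genomes uses anchor density over the
  matched span as a proxy for identity; segments between 90% and ~97%
  identity to a second genome could in principle escape the flag at
  default settings.
* The capacity model assumes equimolar pooling and treats enrichment
  efficiency as a single fraction; it makes no claim about current
  sequencer pricing.
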