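# mitopool

Tag-free multiplex sequencing of complete animal mitochondrial genomes:
pool design, run planning, read simulation, baseline assembly and
sequence-as-tag demultiplexing.

## The idea

Complete metazoan mitogenomes (~14–20 kb, circular) can be sequenced in
multiplex **without synthetic barcodes**. If the pooled specimens are
divergent enough all along their mitochondrial genomes, their reads
assemble into separate contigs, and each contig can be attributed to its
specimen afterwards by comparing it with reference barcode markers (COI,
12S, 16S, CYTB): the sequences themselves act as tags. The catch is the
*if* — pooling decisions must be made before sequencing, from whatever
partial data exist.

`mitopool` provides the desk-side toolkit for that workflow:

* **Screening.** The pairwise p-distance
  `p = mismatches / comparable sites` (pairwise deletion of gaps and N),
  computed on the Folmer fragment of COI (positions 50–700, the ~650 bp
  standard barcode) as a cheap proxy, and in sliding windows (150 bp /
  step 15, or 450 bp / step 45) along full pairwise alignments for the
  definitive check. Windows spanning a one-sided deletion are flagged
  low-information instead of reporting a spurious 0% divergence.
* **Pooling rule.** Pairs with Folmer divergence ≥ 15% essentially never
  show a 450 bp window under 5% divergence; both thresholds are policy
  parameters. `maxPool()` finds the largest mutually compatible pool
  (exact branch-and-bound ≤ 25 specimens), `partitionPools()` splits a
  specimen set into the fewest runs (DSATUR colouring, with an exact
  lower bound).
* **Capacity.** `genomes/run = throughput × mitoFraction /
  (genomeLength × coverage)` with 17 kb genomes and a 50% mitochondrial
  library by default; `capacityTable()` tabulates seven bench-top
  sequencer presets.
* **Validation.** A seeded read simulator for pooled circular genomes
  (per-base error 0.02, haplotype mutation 0.001 with 1/10 indels of
  geometric length, 5% random-DNA contamination, coverage ladders
  10× + 2× steps, single or paired end, full per-read truth records), a
  deterministic de Bruijn unitig assembler (k = 31), k-mer-based contig
  assignment against a reference database, and contig-to-truth overlap
  summaries (fraction of each genome covered by its best contig,
  >33/50/66% counts). A synthetic mitogenome-family generator with
  region-specific rates (rRNA slow, control region fast) supplies
  controlled inputs for everything.

## Worked example

Generate a 6-specimen synthetic family at ancestor-divergence 0.12,
check it is poolable, and push it through the whole in-silico pipeline:

```r
library(mitopool)

fam <- makeFamily(familySpec(6, 0.12, indelRate = 1e-4, seed = 7))
head(fam$truth, 3)
#>   idA idB folmer_proxy expected_pairwise_p
#> 1 T01 T02    0.2611367              0.2208
#> 2 T01 T03    0.2350230              0.2208
#> 3 T01 T04    0.2519201              0.2208
```

Every pair clears the 15% Folmer rule, so one untagged run suffices:

```r
cm <- buildCompatibility(fam$genomes, compatPolicy(mode = "proxy_only"))
cm
#> CompatibilityMatrix: 6 specimens, 15/15 pairs compatible (mode proxy_only)
maxPool(cm)
#> PoolPlan: 6 member(s) [T01, T02, T03, T04, T05, T06], min pairwise evidence 0.2243
runCapacity(throughput = 35e6, coverage = 20, runCost = 1100)
#> $genomesPerRun 51   $costPerGenome 21.37   $raw 51.47059
```

(35 Mb at 20× and a 17 kb genome with a half-mitochondrial library gives
51.47 genome equivalents: 51 genomes, $21.37 each.)

Simulate the pooled run at 40×, assemble, and demultiplex against the
specimens' own COI barcodes:

```r
rs  <- simulatePool(fam$genomes, coverage = 40, readLength = 150,
                    model = errorModel(), seed = 1)
rs
#> SimulatedReadSet: 26578 reads (1376 random/contaminant), single-end
ctg <- assembleReads(rs, k = 31, minCount = 5)
ctg
#> ContigSet: 442 contig(s), total 106124 bp, longest 7016 bp, 0 circular

refdb <- referenceFromGenomes(fam$genomes)
asn   <- assignContigs(ctg, refdb)
table(asn$status)
#> assigned unassigned
#>        6        436

pl <- mapContigsToTruth(ctg, fam$genomes)
ov <- overlapSummary(pl, fam$genomes)
ov$perGenome[, c("genome", "n_contigs", "best_fraction", "covered_fraction")]
#>   genome n_contigs best_fraction covered_fraction
#> 1    T01       122     0.3092698        1.0000000
#> 2    T02        98     0.2207124        0.9978411
#> 3    T03        81     0.4316638        1.0000000
#> 4    T04        51     0.4454603        0.9998095
#> 5    T05        42     0.3376508        0.9939683
#> 6    T06        48     0.1779048        0.9947302
ov$poolCounts
#> gt33 gt50 gt67
#>    3    0    0
```

Reading the output: every contig that was assigned went to the correct
specimen (the COI-bearing contig of each genome scores ~1 against its
own barcode and ~0 against the others), ~99–100% of every genome is
covered by some contig, and no contig is chimeric. Best *single-contig*
sizes, however, top out well below the genome length: conserved rRNA
and tRNA regions still share 31-mers between specimens even at these
divergences, and every shared k-mer breaks unitigs in the pooled graph.
The methods vignette (`vignettes/mitopool-methods.Rmd`) quantifies this
structural limit of unitig assembly at k = 31 and explains why
overlap-based assemblers do not suffer from it; for real pool
validation, export the simulated reads with `writeFastq()` and feed any
external assembler's contigs back in via `readContigs()`.

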