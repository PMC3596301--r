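# snoEvol

Comparative-genomic analysis of polycistronic box C/D snoRNA gene
clusters.

In many fungi, box C/D snoRNAs are encoded in tandem inside the introns of
a non-coding host gene: each snoRNA carries a box C (TGATGA) near its 5'
end, a box D (CTGA/ATGA) near its 3' end, and an antisense guide element
whose reverse complement pairs with rRNA to direct 2'-O-ribose
methylation. Across species, the *introns* hosting these snoRNAs come and
go: they degenerate in place (de-intronization), are physically deleted
leaving residual stubs (genomic deletion), are excised as complete DNA
units and re-inserted elsewhere in the genome flanked by short direct
repeats (excision-and-insertion), recombine into chimeric introns, and
gain new snoRNA-free introns marked by 8-12 bp inverted repeats at the
insertion junction. Internal exons are lost, leaving "complex introns" —
several introns in juxtaposition — that are removed by stepwise splicing
from the 5' end.

snoEvol implements this entire comparative inference as a tested R
pipeline, together with a genome-evolution simulator that generates
synthetic clusters evolved along a phylogeny under exactly these six
mechanisms with a complete ground-truth event log, so every stage of the
pipeline can be validated end to end.

## What the package does

* **Simulation** (`simulationConfig`, `buildAncestralCluster`,
  `evolveAlongTree`, `simulateEvolution`, `applyDeletionLoss` and the
  other forced-event operators, `simulateTranscripts`) — synthetic
  fungal-like genomes carrying a snR78..snR72-style cluster, evolved
  along a newick tree under per-branch event probabilities plus neutral
  point mutation, with truth annotations, architectures and an event log.
* **snoRNA detection** (`scanBoxMotifs`, `scoreGuide`, `assignFamily`,
  `detectChimera`, `scanSnoRNAs`) — box C/D motif pairing, guide-element
  scoring against an rRNA reference, family assignment by global
  alignment, and exhaustive breakpoint scanning for chimeric fusions.
* **Intron annotation** (`findSpliceSignals`, `delineateIntron`,
  `assembleArchitecture`, `detectComplexIntrons`, `annotateGenome`) —
  canonical splice-signal search (GTAAGT donor, TACTAAC branch point,
  first-AG acceptor), intronic/exonic classification of each snoRNA,
  exon/intron architecture assembly and complex-intron flagging.
* **Cross-species comparison** (`buildPresenceAbsenceMatrix`,
  `detectResidualStub`, `searchRelocated`, `fitchParsimony`,
  `placeEvents`, `countExonLoss`, `compareClusters`,
  `evaluateEventRecovery`) — the intron presence/absence matrix,
  mechanistic loss/gain evidence, and branch-placed, evidence-classified
  evolution events.
* **Junction repeats** (`findDirectRepeats`, `findInvertedRepeats`,
  `annotateEventJunctions`) — target-site duplications and short
  inverted repeats at insertion junctions.
* **Splicing inference** (`resolveProduct`, `classifyProducts`,
  `testStepwise`, `noteAlternativeModel`) — removed/retained intron sets
  of spliced transcripts by exhaustive hypothesis testing, product-class
  tallies, and the stepwise 5'-to-3' splicing test.

## A worked example

```r
library(snoEvol)

## simulate 12 species from a seven-snoRNA ancestral cluster
sim <- simulateEvolution(simulationConfig(seed = 42))
nrow(sim@eventLog)
#> [1] 32

## recover the events from the leaf genomes alone
res <- compareClusters(sim@genomes, sim@tree, sim@references, sim@rRNA)
cellStates(res$matrix)["snR77", 1:4]
#>        sp01        sp02        sp03        sp04
#> "relocated"  "intronic" "relocated"  "intronic"

head(eventsAsDataFrame(res$events), 3)
#>            kind branch     subject evidence_type confidence
#> 1 recombination     n2 snR76|snR75 chimera_split  supported
#> 2 recombination    n10 snR75|snR74 chimera_split  supported
#> 3 recombination    n11 snR75|snR74 chimera_split  supported

evaluateEventRecovery(res$events, sim@eventLog)[c("precision", "recall")]
#> $precision
#> [1] 1
#> $recall
#> [1] 1
```

Each row of the events table is one mechanistically classified change —
its kind (one of the six mechanisms), the tree branch it is placed on
(named by the child node), the snoRNA family or exon it affects, and the
sequence-level evidence that supports it (a residual-stub alignment, a
relocated locus, degraded splice signals, a chimera split, junction
repeats, or intron juxtaposition). On this benchmark run all 32 true
events are recovered with no false positives.

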