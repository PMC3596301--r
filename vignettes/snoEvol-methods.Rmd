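---
title: "Models and methods behind snoEvol"
author: "snoEvol authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind snoEvol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

snoEvol studies how the introns that host tandem box C/D snoRNAs evolve:
how they degenerate, get deleted, move, recombine, and how the complex
introns left behind by exon loss are spliced. This vignette explains the
models the package implements, the defaults it ships with and why, what
the bundled simulator does and does not emulate, and the known
limitations of the inference. Every empirical number quoted here is
computed by the package's own test suite or by
`scripts/acceptance.R`; nothing is asserted that the code does not
measure.

## The biological objects

A **box C/D snoRNA** is modelled as: a short 5' leader, an exact box C
(`TGATGA`) within 10 nt of the 5' end, internal sequence, a 10-21 nt
**guide element** that is the reverse complement of an rRNA segment, an
exact box D (`CTGA`) immediately 3' of the guide, and a short trailer.
An **intronic snoRNA** sits inside a spliceosomal intron of the
polycistronic host gene: a GT-initial donor (consensus `GTAAGT`), a
branch point (consensus `TACTAAC`) in the 3' part of the intron, and an
AG acceptor that is the *first* AG downstream of the branch point — the
spliceosome's AG-scanning rule, which the simulator honours by keeping
the branch-to-acceptor tract AG-free.

A **cluster architecture** is the tiled exon/intron layout of one
polycistronic cluster; two or more introns in juxtaposition with no
intercalating exon form a **complex intron**.

## Six event mechanisms

The simulator and the comparative classifier share one event taxonomy:

| kind | genomic change | diagnostic evidence |
|---|---|---|
| de-intronization | donor, branch point and acceptor degraded in place; the snoRNA stays, now exonic | snoRNA present, no qualifying splice triple |
| deletion loss | intron and snoRNA deleted except a 5' residual stub | stub alignment at the exon-exon junction |
| excision-insertion | the full intron unit (GT..AG, snoRNA included) excised at the DNA level and inserted into a staggered double-strand break far from the cluster | relocated locus; target-site duplication (3-8 nt direct repeat) flanking the insert |
| recombination | two families' introns fuse into one chimeric intron: box C and 5' part from one parent, guide, box D and 3' part from the other | chimeric snoRNA with a recoverable breakpoint |
| exon loss | an internal exon deleted, juxtaposing its neighbour introns | complex intron where relatives keep the exon |
| intron gain | a new snoRNA-free intron with full-strength signals inserted into an exon or into a snoRNA between guide and box D, with an 8-12 bp inverted repeat split between the upstream exon end and the intron's far end | exact-signal intron with no snoRNA anchor; junction inverted repeat |

## The simulator and its defaults

`simulationConfig()` defaults define the study conditions used by every
benchmark in this package: a balanced 12-species tree, seven snoRNA
families (the snR78..snR72 layout; three-family configurations use the
snR41-snR70-snR51 names), snoRNAs of 70-100 nt, introns of 60-200 nt,
exons of 5-80 nt, 2 kb background flanks, a 1.5 kb generated rRNA decoy
for the guides, and 2% point substitution per site per unit branch
length with functional motifs (boxes, guides, splice signals, planted
repeats) protected from mutation. Per-branch event probabilities
(0.07 for de-intronization, deletion and excision-insertion, 0.06 for
recombination, 0.09 per internal exon for exon loss, 0.04 for intron
gain) were chosen once so that a default run accrues roughly thirty
events spread over all six kinds; measured across seeds a run logs 22-36
events. Branch lengths absent from the tree count as 1. The ranges for
residual stubs (5-25 nt), direct repeats (3-8 nt) and inverted repeats
(8-12 nt) follow the biology the package models.

Design choices worth knowing:

* **One event per element per lineage.** Conflicting events on one
  element in one branch are resolved by the fixed priority deletion >
  recombination > excision-insertion > de-intronization > intron gain >
  exon loss, and an element changed by an event is inert in its
  descendants. Convergent events still arise in parallel lineages —
  deliberately, since independent losses of one family are a real
  phenomenon the classifier must face.
* **Insertion-site sparsity.** Excised units re-insert at least 900 nt
  from the cluster and at least 700 nt from any previously relocated
  unit; if no such site exists the event silently does not happen. In a
  real genome independent insertions are effectively unlinked; the short
  simulated flanks must not make them adjacent, or they would form
  spurious clusters no method could justify splitting.
* **Recombination cuts** give each parent at least 30 nt; fusions with a
  sub-25 nt minor segment would be undetectable by any split-alignment
  method and are not what the real chimeras look like.
* **Exon loss** is only drawn for exons flanked by plain family-hosting
  introns: the comparative count scores juxtaposition of snoRNA
  introns, and a loss next to an anonymous gained intron has no
  cross-species key.
* Background sequence is i.i.d. uniform over A/C/G/T; GC content, indel
  mutation, codon structure and within-species polymorphism are not
  modelled. Adjacent introns abut with zero overlap; shared-nucleotide
  boundaries between juxtaposed introns are not simulated (an
  `allowSharedNt`-style relaxation was considered and rejected because
  the splicing chemistry of a shared boundary is ambiguous).
* Mutation protection of motifs is the default because the real data
  show motif conservation and protection makes parameter-recovery tests
  interpretable; with protection off, degraded motifs are annotated as
  what they have become (an intron whose donor decays is, genuinely, no
  longer an intron).

What a passing benchmark does **not** show about real data: real
assemblies have repeats, indels, GC structure, fragmented contigs and
sequencing error; real snoRNAs have degenerate boxes (`ATGA` box D
variants, C'/D' boxes) and real splice signals vary more than the
consensus. The detection thresholds below are configurable for that
reason.

## Detection defaults and the reasoning behind them

* **Box scanning**: box C `TGATGA` with at most 1 mismatch, box D
  (`CTGA`/`ATGA`) exact — box D is only 4 nt, one mismatch destroys its
  specificity. Box separation 50-150 nt; candidates with larger
  separations are tested for an embedded gained intron between guide and
  box D (the pattern produced when an intron inserts inside a snoRNA).
* **Guide scoring**: longest window whose reverse complement matches the
  rRNA with 0 mismatches, at least 10 nt, and the guide must abut box D
  on its 5' side. The abutting requirement is structural (that is where
  guides sit) and is also what keeps random box pairings out: a
  candidate is only reported if it has a guide and either a family
  assignment or a chimera split.
* **Family assignment**: global alignment with unit match/mismatch
  scores and affine gaps (open 2, extend 1); identity is matches over
  the longer length. The call threshold is 0.7: random sequences reach
  ~0.6 under gapped alignment, so a 0.6 threshold produces false family
  calls.
* **Chimera detection** aligns every 5'/3' split (each segment globally
  within its best reference region) and is attempted for every
  candidate: a genuine fusion can still reach 0.9 identity to its major
  parent. A split is accepted only when both segments are at least 25 nt
  at 0.75 identity, belong to different families, and match their
  parents at least as well as the whole candidate matches any single
  family.
* **Intron delineation** demands a GT-initial donor scoring at least 5/6
  against `GTAAGT`, an exact `TACTAAC` branch point, the first AG 5-100
  nt downstream of it, intron length 40-500 nt, and a combined score of
  at least 14/15. Fungal splice signals are nearly invariant, so the
  strict default is biologically appropriate — and necessary: at looser
  thresholds (donor+branch score floor around 10), random GT / branch /
  AG triples near a de-intronized snoRNA qualify with double-digit
  percent probability, destroying the intronic/exonic call. The search
  never crosses a neighbouring snoRNA. Ties go to the shortest intron,
  then the leftmost donor, then the most 3' branch point.
* **Cross-species refinement**: point substitution never moves
  positions, so orthologous host introns keep their donor at the same
  offset from the snoRNA. A species whose donor offset disagrees with
  the offset shared by two or more others carries a spurious triple and
  is demoted to exonic (`refineAnnotations`).
* **Gained snoRNA-free introns** are called only on full-strength
  evidence (exact donor, exact branch, AG, 40-500 nt, 3 nt exonic
  margin): without a snoRNA anchor, anything weaker floods the
  comparison with noise.
* **Cluster membership**: snoRNAs chain into a cluster while effective
  gaps are at most 700 nt, where the effective gap subtracts
  exact-signal introns lying in it (gained-intron pileups legitimately
  widen a cluster's internal gaps). Copies beyond that are relocated
  loci; their boundaries are refined by local alignment against an
  intact ortholog unit.
* **Stub evidence** is an ungapped match anchored to either end of the
  reference intron, at least 8 nt at 0.85 identity. Free local alignment
  at the 5 nt / 0.8 level finds a "stub" in almost every random 100 nt
  junction; 8 nt anchored matches have a ~4% background. Stubs shorter
  than 8 nt go undetected and their deletions are reported with
  `inferred` confidence.
* **Relocation search** (`searchRelocated`) requires 0.7 identity over
  0.8 of the unit.

## Event placement

The matrix rows are reconstructed with an irreversible (Dollo-style)
model ordered intronic → exonic → absent, rooted intron-rich: a node
takes the strongest state among its informative descendants, and every
downward transition on an edge is an event. Plain Fitch parsimony —
which the package also provides as `fitchParsimony` — was evaluated and
rejected for this role: it systematically merges convergent losses of
one family into a single fictitious ancestral change, and independent
losses of the same family are exactly what this system produces.
Chimeric and relocated cells are uninformative for the family's own
row (their absence is explained by the recombination or
excision-insertion event that owns the evidence), and events are placed
on the stems of the clades that actually exhibit them, so uninformative
leaves never drag an event above its evidence.

Convergent same-family events on sibling branches are separated by
sequence evidence rather than topology: recombinations by breakpoint,
relocations by insertion-site flank identity, de-intronizations by the
relic nucleotides at the degraded signal positions (hamming distance at
most 3 groups leaves into one shared event; independent degradations
differ at about 5-6 of the 15 positions), and deletions by residual-stub
length (grouped within a 3 nt jitter). Gained-intron orthology groups
are built by single-linkage clustering at 0.8 identity of the shorter
copy within the longer, and each group's gain sits on the stem of the
smallest clade containing all carriers. Exon positions are keyed by the
flanking family pair observed adjacent in each species, rooted at the
smallest clade where the pair is visible; a pair absent everywhere it is
visible yields one loss on that clade's stem.

On the benchmark simulation (12 leaves, seed 42, 2% mutation, motifs
protected, 32 logged events) the pipeline recovers (kind, branch) event
pairs with precision and recall of 1.0; across other seeds precision
stays at or above 0.9 and recall between 0.86 and 0.96. The residual
errors are mostly intrinsic: a later event can destroy the evidence of
an earlier one (an exon-loss witness deleted in every descendant, a
de-intronized intron spuriously re-qualified), and no method working
from the leaves can recover what is no longer there.

## Splicing inference

`resolveProduct` tests all 2^k removed-subset hypotheses by global
alignment (k at most 12 — clusters here have at most seven introns;
correctness is preferred over generality) and accepts the best
hypothesis when its mismatch rate is at most 0.03, the quality expected
of single-pass transcript reads. Ties prefer fewer removed introns,
then the lexicographically smallest set. Note one interplay of these
defaults: a fully spliced product of a short cluster can be ~130 nt, and
at a 1% error rate about 3-4% of such reads carry four or more errors,
just over the 3% gate, so batch-level truth recovery sits at ~99% rather
than 100% — the dropped reads are rejected, not mis-assigned. The
stepwise test is then purely set-combinatorial: consistent exactly when
every removed set is a 5' prefix of the intron order. The single-donor /
alternative-acceptor model predicts the same product classes, so
`noteAlternativeModel` reports model compatibility but never adjudicates
— from spliced products alone the two models cannot be distinguished.

## Problem sizes used by the checks

The test suite and acceptance script run entirely on simulated data: the
12-leaf benchmark and null runs, 4-species forced-event panels, 200
random junction instances and 200 random 1-kb sequences for the
scanner-vs-oracle equivalences, 10 chimeric fusions at 5% divergence,
500 transcripts at 1% error plus 40 batches of 15 for the stepwise
verdicts, and smaller randomized panels in the unit tests. These sizes
keep a full run in minutes on one CPU while leaving every statistical
check comfortably powered.

## Known limitations

* Event placement is evidence-driven parsimony; rate estimation, dating
  and likelihood-based ancestral reconstruction are out of scope.
* Acceptor positions inherit the first-AG rule, so a substitution that
  creates an earlier AG shifts a called 3' boundary; boundary-sensitive
  steps (relocation flanks, junction widths) therefore rely on
  alignment-refined or donor-side coordinates.
* All features are modelled on the forward strand; reverse-strand
  clusters, H/ACA snoRNAs, structure-aware (covariance-model) search and
  position-weight-matrix splice scoring are not implemented.
* "Absent" means absent from the provided sequence; the package cannot
  distinguish a genuine genomic loss from a gap in a draft assembly.
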