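---
title: "Locating Tnt1 insertion sites from paired-end WGS: methods and design"
author: "tntscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating Tnt1 insertion sites from paired-end WGS: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tntscan)
```

## The problem

Tnt1 is a ~5.3 kb autonomous *copia*-like LTR retrotransposon from tobacco
that has been used for near-saturation insertional mutagenesis of the model
legume *Medicago truncatula*. Each mutant line carries tens of independent
insertions, and finding the one that causes a phenotype requires recovering
the genomic location of every insertion in a plant. Whole-genome paired-end
sequencing makes this a computational problem: every read pair that touches
an element-genome junction is direct evidence for an insertion site.

`tntscan` implements that detection workflow end to end -- read QC,
classification of read pairs against the element's terminal sequences,
junction extraction, assembly of "rescue" mates, mapping of all evidence to
a reference genome, clustering into insertion loci with a high/low
confidence call, and zygosity estimation -- together with the companion
statistics a segregation study needs (Mendelian chi-square test, fold
coverage, comparison of insertion-site sets). Because real mutant-line data
is large and external, the package also ships a seeded simulator that plants
insertions with known positions and zygosity; every claim the package makes
about itself is tested against that ground truth.

## The read-pair model

The element carries identical 610 bp long terminal repeats (LTRs). The
first and last `terminal_length` (default 90) bases of the element are used
as left-end (LE) and right-end (RE) baits. Each read is aligned locally to
both baits on both strands and labelled:

* **element** -- the best bait hit covers the read end to end (within
  `full_match_slack`, default 3 bases);
* **hybrid** -- the hit spans at least `min_element_match` (15) bases at
  `min_identity` (0.90) or better, touches the bait's *outward* edge (the
  edge where genome meets element), reaches the read's edge on the
  element-continuation side, and leaves at least `min_genomic_tail` (20)
  bases of genomic sequence; the read straddles a junction;
* **genomic** -- anything else.

Mate labels combine into the five canonical pair types: 1
(element-element), 2 (genomic-genomic), 3 (hybrid with an element mate), 4
(genomic with a hybrid mate), 5 (genomic with an element mate). Types 3-5
carry the information: hybrid reads give base-accurate junctions, and the
genomic mates of type 4/5 pairs ("rescue reads") come from the flank next
to an insertion and are assembled into unitig nodes that extend the
evidence. Two taxonomy corners the five types do not name are resolved as:
hybrid-hybrid is recorded as type 3 (both junctions kept as evidence) and
hybrid-genomic as type 4.

Because the two LTR copies are identical, a read can only be assigned an
end by junction geometry, not by which physical LTR copy it came from. Two
consequences are accepted rather than hidden. First, reads that straddle
the element's *internal* LTR boundaries look like hybrids whose "genomic"
tail is element interior; they are classified hybrid but their fragments do
not map to the reference and are discarded at the mapping stage (they
appear in the unmapped count). Second, reads from deep inside the element
match neither 90 bp bait and are labelled genomic; the pairs they form are
inert for locus calling because their sequence does not map to the
reference either. Both behaviours mirror what a terminal-bait classifier
can know, and both are exercised by the tests.

### Arbitration of weak double matches

A rare genomic locus can resemble a terminal's outward edge closely enough
(15 bases at 90% identity) that every read whose end falls across it
becomes a false hybrid -- and because all those reads agree on one
position, they can cluster into a false high-confidence locus. The package
arbitrates with a reference-placement test (`drop_reference_hybrids()`): a
genuine junction read can never be placed end to end on the reference
(its element portion does not exist there), while these impostors place
with at most a few sequencing errors. Hybrid calls whose full read places
within the mismatch budget (`max_mismatch`, default 6) are dropped and
counted.

## Alignment machinery

All alignment is done internally so the pipeline has no binary
dependencies. Two layers exist by design:

* `smith_waterman()` -- an exact quadratic-time local aligner with a linear
  gap penalty (defaults +1/-2/-3), used directly on the short terminal
  baits and serving as the oracle in tests;
* `seeded_local_align()` -- a k-mer seeded aligner over an indexed target
  set (`build_kmer_index()`), which seeds exact k-mer hits on both strands,
  extends each seed band with the same Smith-Waterman scoring on a target
  window, and reports hits whose scores therefore equal the exact aligner's
  on that region. Defaults: k = 13 for genome mapping, k = 11 for terminal
  matching -- seeds must fit inside a 90 bp read carrying one error.

Ties are broken deterministically (smallest query start, then target
start); hits below score 1 are never reported; `N` mismatches everything,
and k-mers containing `N` are skipped. Overlapping hits on the same target
are merged (best first, >50% query overlap) *except* when scores tie, so
that a query with two equally good placements is still visible as
ambiguous downstream; multi-mapping evidence is discarded and counted, not
randomly placed. Coordinates are 0-based half-open internally and 1-based
only in the insertion report (BED export converts back).

For the bulk placement of type 2 pairs used by zygosity estimation, a
dedicated fast path (`place_read_pairs()`) places whole reads by exact
k-mer seeding plus mismatch counting instead of full dynamic programming;
with ~0.1% substitution error, full-length placement with a small mismatch
budget is the appropriate (and much faster) model.

## Assembly of rescue reads

Rescue reads are assembled per LE/RE group with a built-in de Bruijn unitig
assembler (`assemble_nodes()`): canonical k-mers (k = 21, odd so no
palindromes), a multiplicity floor (`min_kmer_count`, default 2; 1 in
error-free tests), maximal non-branching paths as nodes, and clipping of
dead-end branches shorter than 2k. Nodes are emitted in canonical
orientation (lexicographic minimum of a sequence and its reverse
complement) and sorted, which makes assembly deterministic and invariant
under reverse-complementing the input -- the price is that a node equals
its source sequence only up to reverse complement, which every consumer
tolerates because mapping is strand-aware. No scaffolding or bubble
popping is attempted: the targets are short single-copy flanks.

## From evidence to loci

Hybrid fragments and nodes are mapped to the reference
(`map_evidence()`, identity >= 0.95, mapped length >= 20). The junction
breakpoint is taken from the junction-proximal end of the mapped interval:
for a hybrid, the fragment edge that touched the element, carried through
the hit strand; for a node, the element-facing end implied by its LE/RE
group (an upstream flank faces the element at its high-coordinate end).

Evidence is clustered per chromosome by single linkage
(`cluster_evidence()`), merging LE-side and RE-side evidence into one locus
-- both junctions belong to one inserted element, offset only by the
target-site duplication (TSD, ~5 bp). The cluster position is the median
member breakpoint (lower middle on ties), which in practice tracks the
base-accurate hybrid reads.

**The clustering window is 600 bp, not a small junction-sized window.**
This is the one genuinely structural tuning decision in the package, so the
reasoning is spelled out. Hybrid breakpoints land within a few bases of the
junction. A rescue-mate node, however, *cannot* reach the junction: the
recruiting fragment's inner ~`insert_mean - 2 * read_length` bases are
unsequenced, so the node's element-facing end sits ~320 bp (plus insert-
length spread) short of the junction for a 500 bp library of 90 bp reads.
With a window much smaller than that offset, node evidence forms satellite
clusters 250-450 bp from the junction; at sufficient coverage three such
nodes make a spurious high-confidence locus, and below that they litter the
report with low-confidence satellites. A 600 bp window (about one insert
length) absorbs the node offset and both junction sides while remaining far
below the spacing of distinct insertions in this mutagenesis system (tens
of insertions per ~400 Mb genome); the locus position stays
hybrid-dominated via the median. The FST deduplication window in the
statistics module remains 100 bp, because flanking-sequence tags are
junction-accurate coordinates and need no allowance for insert geometry.

Confidence follows the three-support rule: a locus with at least
`hc_min_support` (3) distinct supporting reads/nodes is high confidence
(HC), anything less is low confidence (LC); each physical read or node
counts once. Loci are then numbered deterministically -- HC before LC,
chromosomes in reference order with unplaced scaffolds after, ascending
position, support and member id as final tie-breaks -- as `Insertion-1`,
`Insertion-2`, ...

### Zygosity

A genomic fragment "spans" a junction when its two placed mates lie
strictly on opposite sides of the breakpoint. A homozygous insertion has no
intact reference allele, so nothing can span it (a 500 bp fragment cannot
bridge a 5.3 kb element); a heterozygous one is spanned by fragments from
the unmodified haplotype at roughly half the total depth. Calls:
homozygous when zero fragments span and junction support is at least 3;
heterozygous when at least `min_span` (3) fragments span; undetermined
otherwise. The thresholds are this package's choice; the underlying signal
(junction-site coverage by intact genomic pairs) is standard.

## The simulator and what it does (not) emulate

`simulate_dataset()` pins an entire ground-truthed experiment to one seed:
an i.i.d. random genome at a chosen GC (default 1 Mb, GC 0.5), a synthetic
5,300 bp element with identical 610 bp LTRs (generated once at a fixed
internal seed so it shares no sequence with any simulated genome; the real
element FASTA can be supplied instead), planted insertions with a 5 bp TSD
(typical for *copia*-family elements) in random orientation, and paired-end
reads: 90 bp mates from Normal(500, 50) fragments drawn uniformly along the
haplotypes at 40X haploid coverage with i.i.d. substitution errors at 0.1%
(Q35 bases, errored bases written at Q15). These defaults are the sequencing
design of the study the pipeline reproduces. Insertions are kept 2 insert
lengths from chromosome ends and 4 insert lengths apart -- real insertions
in this system are orders of magnitude sparser -- so that simulated loci are
individually resolvable.

The simulator is deliberately simple where simplicity does not change what
is being tested: no indels, no quality-profile or GC bias, no PCR
duplicates, no somatic mosaicism, no truncated or rearranged element
copies, and a repeat-free random genome. Passing the recovery tests
therefore demonstrates the pipeline's logic (classification geometry,
assembly, clustering, confidence and zygosity rules) under the stated error
model -- it does not demonstrate robustness to repetitive genomes,
polymorphic element copies, or structurally messy libraries, which is
exactly the caveat a reader should carry to real data.

## Numerical and procedural choices

* "Low quality base" is undefined in the source material; the QC filter
  uses the conventional Phred < 20 with the documented >50% removal rule
  (a pair is dropped when either mate exceeds the fraction, so downstream
  logic never sees orphans). Adapter trimming is out of scope: inputs are
  assumed to be "clean" reads. The FASTQ dialect is fixed to Phred+33 and
  other encodings are rejected, not guessed.
* The segregation test is Pearson's goodness of fit without continuity
  correction against an arbitrary expected ratio (default 3:1), with the
  upper-tail p from the chi-square distribution (df 1). The uncorrected
  statistic is the one that reproduces the published value for the 248:87
  table (0.168); for the published 258:70 table no standard variant
  reproduces the printed 2.756 (uncorrected gives 2.341, Yates 2.150), and
  the implementation is intentionally not tuned toward it.
* Fold coverage is clean bases over genome size, reported unrounded and as
  the floored integer fold (the convention under which 44.06 prints as
  44X and 41.43 as 41X).
* All randomness flows through explicit integer seeds
  (`withr::with_seed`), so simulation is bit-reproducible; detection itself
  contains no randomness, and identical inputs plus an identical
  configuration give byte-identical output tables.

## Problem sizes used in validation

The shipped tests run the full pipeline at the study design (1 Mb genome,
20 homozygous insertions, 40X, five seeds) for recovery, precision and the
HC-support floor; a 2X run for the demotion property; 500 kb genomes with
half-heterozygous insertions (five seeds) for the zygosity signal; and
smaller constructions for classification completeness, assembler soundness
and aligner-oracle equivalence. These sizes were chosen as the smallest at
which each property is meaningfully exercised at its stated threshold.

## Known limitations

Truncated or internally deleted element copies are not modelled or
detected; classification from pre-aligned BAM soft-clips is not supported;
multi-mapping evidence is discarded rather than rescued, so insertions in
repeats are invisible by construction; and the LC tier is reported but
deliberately not quantitatively calibrated -- in the source study the
meaning of the numerous LC loci was itself unclear.
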