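---
title: "Methods and design of gvcompare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of gvcompare}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gvcompare)
```

`gvcompare` packages the comparative-genomics workflow used to characterize
newly sequenced granulovirus (betabaculovirus) genomes. This vignette is the
package's own account of the methods: the conventions and models each stage
implements, the tunable parameters and why their defaults are what they are,
what the synthetic-data generator does and does not emulate, and the design
choices made where the underlying publications leave the procedure open.

## Coordinates and the circular genome

Baculovirus genomes are closed circles reported in linearized form. All
coordinates in the package are 1-based and inclusive; an interval with
`start > end` on a circular genome wraps through the origin. The community
convention anchors the map at the granulin gene: *orf1* starts at nt 1 on the
plus strand, and "clockwise" means the granulin gene's transcription
direction. `anchor_and_number()` implements exactly this: rotation (plus a
strand flip when the anchor was called on the minus strand) followed by
renumbering in footprint order. Anchoring is a pure re-coordinatization — a
property the test suite asserts by re-extracting every protein after
rotation.

`N` is accepted in input sequences but excluded from composition
denominators, so GC content remains well defined on assemblies with
ambiguity positions; `U` is rejected because the toolkit is DNA-only. The
only export that changes coordinate conventions is BED (0-based half-open),
converted at the writer boundary.

## ORF annotation

`enumerate_candidate_orfs()` performs a six-frame scan for *maximal* ORFs:
from the first in-frame ATG after the preceding in-frame stop, through the
next in-frame stop. One ORF per locus matches how compact viral genomes are
annotated in practice; enumeration of every internal ATG is available behind
`all_starts = TRUE` for completeness. Circularity is handled by scanning the
doubled sequence and deduplicating by start position modulo the genome
length; an "ORF" longer than the genome itself is rejected as degenerate.
The stop codon is counted in `length_nt`, so the default 150 nt threshold
corresponds to 49 aa plus stop. The published numbers this pipeline aims at
are stated in nucleotides, and either stop convention is consistent with
them, so the package fixes one and documents it.

The published selection rule — ORFs "with minimal overlap" — is not an
algorithm, so the package operationalizes it as a greedy longest-first
selection: candidates are taken in decreasing length (ties: smaller start,
then plus strand) and kept only if their circular overlap with every
already-kept ORF is at most `max_overlap_fraction` (default 0.5) of the
shorter of the two. The 50% default is deliberately permissive because real
betabaculovirus annotations retain adjacent overlaps above 100 bp between
ORFs of a few hundred nt. Published annotations also occasionally rescue an
ORF below the length threshold on homology evidence; `annotate_genome()`
accepts such a rescue list by coordinates rather than hard-coding any gene.

Coding fraction is the union of ORF footprints over genome length, computed
with interval arithmetic (IRanges) and cross-checked in the tests against a
per-base bitmap. Adjacent-overlap statistics consider consecutive ORFs in
anchored order, including the circular last–first pair.

## Protein homology without BLAST

At the scale of one viral proteome (~100–130 proteins), heuristic seeded
search buys nothing, so homology is computed by exact affine-gap dynamic
programming (Gotoh) in C++: BLOSUM62, gap open 11, gap extend 1 — the
familiar protein-BLAST scoring — with a raw-score threshold (default 50)
standing in for an E-value cutoff. Exactness is what makes the module
testable: the suite checks score-identity against an independent
dynamic-programming implementation on hundreds of random pairs, and the
traceback is pointer-based rather than score-matching, so reported
alignments always rescore to their reported score.

Percent identity counts identical columns over aligned columns, gap columns
included in the denominator — the conservative convention; a
`match_cols` denominator is available since published identity figures
rarely state their convention, and the two can differ by several points on
gappy pairs.

Orthologs between two annotated genomes are reciprocal best hits under local
alignment, a one-to-one mapping. Gene classes are assigned by panel
priority: an ORF hitting the core-gene panel is `core` regardless of other
hits, then lepidopteran-shared, then betabaculovirus-specific, then any
other homolog; ORFs hitting nothing are `unique`. The per-family
presence/absence table is reported alongside, since "all 37 core families
present" is the claim such analyses actually make.

## Gene parity, collinearity, and inversions

Parity coordinates are ordinal ranks, not nucleotide positions — relative
gene location is what the parity-plot method compares. The rank origin of
the second genome is rotated so the anchor ortholog is rank 1 in both; if
the anchor is unpaired, the rotation minimizing the summed circular rank
discrepancy is chosen (deterministically, smallest such rotation).

The collinearity score is the fraction of consecutive ortholog pairs
(ordered by genome-A rank, circular wrap included) whose genome-B rank
advances by exactly +1 modulo the genome-B ORF count: 1.0 for perfectly
conserved order, about 1/(n−1) for a random permutation. Inversions are
maximal runs of at least `min_run = 3` consecutive pairs with strictly
decreasing partner ranks — three reversed pairs being the minimum evidence
that separates a segmental inversion from a singleton transposition.
Nucleotide spans are measured in genome-A coordinates, boundary genes
inclusive, which is stated here because published "x kb inversion" figures
rarely define their measurement. Strand flips without order reversal are
biologically distinct events and are reported separately, never as
inversions.

## Repeat regions, palindromes, hairpins

Non-hr replication-origin candidates in betabaculoviruses are tandem arrays
of large imperfect direct repeats with nearby palindromes in AT-rich
intergenic spacers. The finder seeds on exact 8-mer matches at candidate
periods, extends each seed into a self-alignment of the sequence against
itself at that period using an X-drop rule (match +1, mismatch −3, stop 10
below the running maximum — boundaries sit at the score maximum, keeping
region edges tight), then validates copies against the array consensus:
every reported full copy must stay within `max_mismatch_fraction` (default
0.2) of the consensus; edge offenders are trimmed and an interior offender
splits the array. Because a k-copy array is always also a k/2-copy array at
twice the unit, overlapping candidate regions are resolved by most full
copies first, so the fundamental period wins. A trailing partial copy of at
least 40% of the unit sets the truncated-copy flag — the threshold chosen to
reproduce the "truncated imperfect repeat" calls that appear in published
non-hr descriptions.

Palindromes (inverted repeats) are scanned by growing arms outward around
every possible loop placement (loop ≤ 10 nt, arm ≥ 6, arm mismatch fraction
≤ 0.2), with overlapping reports collapsed to the highest-scoring. Hairpins
are predicted by Nussinov-style base-pair maximization with Watson–Crick
pairs only (no G:U — the substrate is DNA), minimum loop 3; among co-optimal
structures the traceback deterministically prefers pairing the 5'-most base
with its most distal admissible partner, which favors contiguous stems. No
thermodynamic parameters are involved: the output is a structural sketch of
the kind published alongside non-hr alignments, not a folding energy.

Classification is rule-based. A region is `non_hr` when it has at least two
direct-repeat copies, is AT-rich (≥ 0.6 by default; AT content is evaluated
on the region itself, matching how per-region AT percentages are reported),
and has a palindrome or a ≥ 4-pair hairpin within or adjacent to it. It is
`hr_like` — which takes precedence, being the more specific architecture —
when a period-consistent palindrome (arm ≥ 8) sits mid-unit (central 40%) in
every full copy, one disrupted unit being tolerated in arrays of three or
more copies because these are *imperfect* palindromes. The period-consistency
requirement exists because AT-rich sequence grows incidental palindromes
freely; requiring the same palindrome at the same unit offset in (almost)
every copy is what distinguishes hr architecture from a repeat array that
merely brushes against a palindrome.

## Promoter motifs

Published genome tables annotate early (E) and late (L) promoters within 150
nt of the start codon without defining the motifs; the package adopts the
standard baculovirus conventions — late: TAAG; early: a TATA box followed by
a CAGT or CATT initiator at a 20–40 nt gap — and makes every piece
configurable, because the original criteria are not recoverable from the
text. The window defaults to 150 nt on the coding strand, overlapping
upstream coding sequence by default (these genomes are compact);
`intergenic_only = TRUE` restricts to intergenic sequence. Every hit reports
the literal motif sequence and its offset, and the suite asserts
self-consistency (the motif occurs at the reported coordinates) and
invariance under re-anchoring.

## Concatenated-protein phylogeny

The published analyses build maximum-likelihood trees from concatenated core
proteins. This package deliberately substitutes a distance pipeline:
Poisson-corrected distances `d = −ln(1 − p)` (p = mismatch proportion over
mutually non-gap columns; pairwise deletion by default, complete deletion by
flag), canonical neighbor joining, and bootstrap support by column
resampling. The trade is transparency for sophistication: every stage has a
closed form or an exact oracle (additive matrices must be recovered
perfectly, and the tests enumerate random weighted trees of up to 8 taxa to
assert exactly that), determinism is trivial to guarantee, and
topology-level claims — which genome is sister to which — are what the
comparative analysis actually uses. No numerical agreement with ML branch
lengths is claimed. Negative NJ branch lengths (possible on non-additive
input) are clamped to zero with the deficit moved to the sibling edge. For
unaligned input blocks the package calls mafft; equal-length blocks (such as
the simulator's, which has no indel process) pass through unchanged. The
supermatrix can be exported for external ML tools via the protein FASTA
writers.

## The synthetic-data generator

`simulate_annotated_genome()` builds a circular genome in the image of a
betabaculovirus: default 60 kb with 60 ORFs (real genomes run 80–180 kb with
100–180 ORFs; the default is scaled down so that a full simulate–analyze
cycle completes in seconds while preserving the density regime), background
and coding base composition targeted at 37.8% G+C (the base-level draw is
solved so that the realized composition hits the target *after* stop-codon
rejection, which would otherwise bias GC upward by about one point), ORFs of
300–1500 nt on both strands, and a 15% chance that consecutive ORFs overlap.

Three constructions make the planted truth exactly recoverable by the
package's own annotation conventions, and they are the part of the generator
most worth knowing about:

* an in-frame stop guard (TAA) immediately 5' of each planted ATG, so the
  maximal-ORF rule cannot extend a start upstream;
* overlaps built from frame-compatible junction patterns — `ATGA` for
  tandem plus-strand pairs (the next ORF's ATG inside the previous TGA
  stop), its reverse-complement mirror for minus-strand pairs, and abutting
  start codons for head-to-head pairs — so shared sequence is valid in both
  frames;
* a post-construction repair pass that walks upstream in frame from every
  planted ATG and mutates away any ATG that precedes the first stop (under
  constraints that never break another planted ORF).

Repeat regions are planted into two designated large spacers; every repeat
unit opens with an AT-rich cassette carrying stop codons in all six frames
(`TAATTAATTAA`), which prevents the array from spawning spurious long ORFs.
Units destined for non-hr-style arrays are additionally scrubbed of
incidental mid-unit palindromes — a unit with a centered palindrome *is* the
hr architecture, so leaving chance ones in place would make the planted
truth label wrong rather than the detector. `evolve_genome()` derives
relatives by codon-aware substitution (each interior codon is replaced, with
the target probability, by a codon for a different amino acid, never a stop,
so expected protein divergence equals the parameter; codons shared by two
overlapping ORFs are frozen) and by reverse-complementing whole gene blocks
whose boundaries must fall at clean junctions. The generator verifies its
own contract — annotation must recover every planted ORF exactly — and
retries with a perturbed layout rather than emit an inconsistent truth
table.

What the simulator does **not** emulate: indels, recombination, codon-usage
structure beyond GC targeting, homologous-region (hr) networks, gene gain
and loss, and sequencing error. Consequently, green planted-truth tests
demonstrate the pipeline's correctness under its own conventions — exact
ORF-boundary recovery, rank-level inversion detection, ±5 nt repeat-boundary
recovery — not robustness to assembly artifacts or deep divergence on real
data.

## Numerical and degenerate-input choices

Alignment tie-breaks prefer substitution over gap states and are encoded as
explicit predecessor pointers, so results are deterministic across
platforms. The Nussinov traceback's stem-contiguity preference is likewise
deterministic. Saturated distances (p ≥ 1, impossible for finite alignments
but guarded) and distances beyond `max_dist = 10` are capped; a taxon pair
with no mutually ungapped columns is an error naming the pair, not a silent
NA. Genomes shorter than the ORF threshold annotate to an empty candidate
set rather than an error; an empty panel list classifies everything
`unique`; fewer than two ortholog pairs make collinearity an error since the
score is undefined. All generator functions are pure in `(configuration,
seed)`; bootstrap and pipeline runs record their seeds, and identical
configurations reproduce byte-identical reports.

## Problem sizes used by the test suite

The shipped checks run the fixture family (three 60 kb genomes, 60 ORFs
each, seed 1234), 200 random circles of up to 2 kb against the literal
six-frame oracle, 100 random protein pairs of up to 200 aa against the
dynamic-programming oracle, 500 short sequences against exhaustive
nested-structure enumeration, and 50 random weighted trees of 4–8 taxa for
exact additive recovery — sizes chosen so the whole suite exercises every
documented property in roughly a quarter of an hour on one core.
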