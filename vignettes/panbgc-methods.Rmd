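---
title: "Methods: strain-level comparison of biosynthetic gene cluster repertoires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strain-level comparison of biosynthetic gene cluster repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panbgc)
```

## The problem

When several strains of one bacterial species are sequenced, their
secondary-metabolite biosynthetic gene clusters (BGCs) can be compared as a
small pan-genome: some cluster families are carried by every strain (the
*core* secondary metabolome), some by a subset (*auxiliary*), and some by a
single strain (*strain-specific*). Two practical obstacles stand between
raw assemblies and that partition. First, strains must actually belong to
one species, which is checked with a multilocus phylogeny and species-level
OTU binning rather than 16S alone. Second, draft assemblies split many
clusters across contigs, so upstream cluster callers report fragments that
must be re-joined before any counting — otherwise a split cluster inflates
both the cluster count and the strain-specific tally.

`panbgc` implements both steps and the bookkeeping that follows: marker
concatenation and neighbour-joining trees, greedy OTU binning, exact-match
anchor alignment for reference-guided stitching, homology-based family
construction, the core/auxiliary/specific partition and the pairwise
conservation matrix. A packaged six-strain, 48-family presence/absence
table for *Streptomyces albus* supports a desk-scale reproduction of the
published conservation statistics, and a simulator with known ground truth
makes every stage testable offline.

## Multilocus phylogeny

**Concatenation.** Five housekeeping loci (default order `atpD, gyrA,
recA, rpoB, trpB`; `locus_alias()` accepts the `aptD`/`gyrB` spellings
seen in the literature) are trimmed per locus to the minimum length
observed across retained strains — trimming from the 3' end, where
amplicon-style fragments vary — and concatenated in a fixed order. Strains
missing a locus are excluded with a warning rather than padded.

**Identity.** Pairwise identity is computed from a global (Needleman–
Wunsch) alignment with match +1, mismatch −1, gap open 5, gap extend 1,
counting identical A/C/G/T columns over all alignment columns except
terminal runs of gap-containing columns. End-gap exclusion keeps partial
fragments comparable to full-length ones; `N` is never a match. The
scoring is a stated package convention: clustering tools in this area do
not document a single canonical identity definition, so the choice is
explicit and configurable at the alignment layer rather than hidden.

**Distances and trees.** Observed differences `p = 1 − identity` are
corrected with the Jukes–Cantor transform `d = −(3/4) ln(1 − 4p/3)`.
Saturated inputs (`p ≥ 0.75`) raise an error instead of being capped: a
capped distance silently distorts every subsequent neighbour-joining step,
and at within-species divergence saturation indicates a data problem, not
a distance. Trees are built by standard Saitou–Nei neighbour joining with
two determinism rules: ties in the Q-matrix break toward the lowest (row,
column) pair, and negative branch lengths are clamped to zero with the
deficit moved to the sister branch so the joined pair's path length is
preserved. On additive matrices the generating topology and branch
lengths are recovered exactly (this is asserted for 200 random 4–8 taxon
trees in the test suite). Neighbour joining stands in for approximate
maximum-likelihood inference; only topology-level agreement with
likelihood methods is claimed, which is sufficient for the redundancy
screening the tree is used for here.

**OTU binning.** Species-level binning uses the greedy centroid scheme:
sequences are processed by decreasing length (ties lexicographic), each
joins the first centroid at or above the identity threshold (default 0.97,
the conventional species proxy) or founds a new OTU. The assignment is
deterministic, and every member is within threshold of its centroid by
construction.

## Anchor alignment and stitching

**Anchors.** `find_mums()` enumerates maximal unique matches: exact
matches of at least `min_len` bp (default 20, the customary seed length
for nucleotide genome comparison), unextendable in either direction, whose
matched substring occurs exactly once in the query and once in the
reference, searched on both strands. Uniqueness is enforced per strand,
and matches never span `N` — which also means stitching junction spacers
are invisible to later comparisons. Internally the implementation indexes
`min_len`-mers and reads maximal matches off as runs of consecutive seed
hits per diagonal; the test suite checks it against a brute-force
enumeration that walks every diagonal of the character match matrix.

**Chains.** `chain_anchors()` finds the maximum-score collinear chain by
dynamic programming: strictly increasing starts in both coordinates (query
direction reversed on the minus strand), adjacent-anchor overlap trimmed
from the score, ties broken toward the chain starting earlier on the
reference. Chain scores are checked against exhaustive enumeration over
all anchor subsets in the tests.

**Assignment and coverage.** A fragment is assigned to the reference
maximizing chain score normalised by fragment length. The acceptance rule
uses the fraction of the fragment *spanned* by the chain (first to last
anchor, gaps included; default threshold 0.5). Span rather than raw
anchor content is used deliberately: at a few percent nucleotide
divergence the expected fraction of a sequence lying inside exact matches
of ≥ 20 bp is only about `(1 − q)^20 (1 + 19q)` — roughly 0.63 at 6%
pairwise divergence — and short fragments fluctuate well below that, while
the spanned region remains a stable measure of how much of the fragment
the alignment explains. An assignment is flagged ambiguous when the
runner-up reference scores within 10% of the best; ambiguous fragments
are excluded from stitching and kept as separate records.

**Stitching.** Fragments co-assigned to one reference are ordered by the
reference start of their chains, reverse-complemented if on the minus
strand, and joined with a spacer of 100 `N`s (visible, alignment-neutral
junctions). When two fragments' reference intervals overlap by more than
half of the shorter interval the stitched record is flagged as a possible
duplicate or misassembly but still emitted; the end-to-end pipeline
instead keeps such records separate and lets deduplication decide.

## Families, deduplication and the partition

Cluster similarity is the chained-anchor coverage of the shorter sequence
— conservative, near 1 for same-family pairs at within-species divergence,
effectively 0 for unrelated clusters (random ≥ 20 bp exact matches between
kilobase-scale sequences are vanishingly rare). Within a strain, clusters
at similarity ≥ 0.9 collapse to their longest representative (recent
duplicates are near-identical, so 0.9 separates them cleanly from the
~0.6 same-family background). Across strains, families are connected
components of the similarity graph thresholded at 0.5 — single linkage,
which deliberately lets a fragment join its family through any full-length
homolog. Both thresholds are package defaults, stated and configurable;
no published numeric threshold exists for this step.

The partition rule is purely set-theoretic: core = present in all strains,
specific = present in exactly one, auxiliary = the rest. The conservation
matrix counts families shared by each strain pair; percentages are
**floor-truncated** integers with the row strain's total as denominator.
Truncation is not a stylistic choice: the published table is only
reproduced under truncation (e.g. 19/29 → 65%, 20/30 → 66%), and rounding
would contradict it.

The packaged fixture transcribes the published per-family inventories.
One published number is internally inconsistent: the SM8 column total is
printed as 26, but only 24 clusters are attributable to SM8 from the
per-family tables. `reproduce_table2()` reports the derived values and
attaches a note; SM8-denominator percentages are excluded from the golden
tests for this reason.

## The simulator and what it does (not) emulate

`simulate_strains()` generates the inputs of the survey with a known
truth: ancestor sequences per family (GC 0.72, mimicking *Streptomyces*
base composition), per-strain copies mutated at a configurable per-site
substitution probability (default 0.03, so two strains' copies differ at
roughly 6% — the upper end of within-species divergence) with short
1–10 bp indels (rate 5e-4/site), occasional within-strain duplicates
(probability 0.05, mutated at 0.5% from their sibling — recent
duplications), genomes laid out with 10–50 kb GC-matched spacers, and
contig breaks that split a cluster copy with probability 0.1 (about the
fraction of multi-contig cluster annotations in published six-strain
inventories). Cluster fragments end at contig edges, at least 200 bp from
a cluster end (callers do not report arbitrarily small fragments).
Default family counts are 18 core / 14 auxiliary / 16 specific across six
strains, matching the repertoire structure the package is designed to
analyse. Family lengths default to 1.5–3 kb — a desk-scale stand-in for
real 10–150 kb clusters that preserves the anchor statistics that matter
(matches per divergence unit scale with length, so results transfer
qualitatively, not as absolute anchor counts).

One structural guarantee: when the fragmentation probability is below 1,
every family retains at least one intact copy. The reference-anchored
stitching workflow — like the closed-reference-genome study design it
mirrors — requires an intact exemplar somewhere; re-joining a cluster
whose every copy is fragmented requires evidence outside sequence homology
(synteny, curation) and is out of scope. At fragmentation probability 1
the guarantee lapses and every copy is split, which is the configuration
the round-trip tests use with the recorded ancestors as references.

What the simulator does **not** model: gene-level cluster architecture
(promoters, domain order), rearrangements and horizontal transfer within
families, assembly base-calling error, collapsed repeats, and realistic
contig-count distributions. Passing the end-to-end test therefore shows
the pipeline's logic is correct under sequence-level divergence,
duplication and fragmentation — it does not certify performance on real
draft assemblies, where cluster-boundary calls and repeat structure add
noise this package receives from upstream tools.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive throughout, matching GenBank-style
  ranges.
* `jc_distance()` errors on `p ≥ 0.75`; `build_nj_tree()` errors below 3
  taxa and on asymmetric input; `partition_families()` errors on a family
  present in zero strains; `read_fasta()` errors on duplicate ids and
  non-IUPAC characters, naming the record.
* Newick output writes branch lengths with six decimals so files are
  byte-stable; JSON output is key-sorted for the same reason.
* All simulation randomness flows from a single seed in the
  configuration; identical configurations reproduce byte-identical files.

## Problem sizes in the shipped tests

The test suite validates neighbour joining on 200 random additive trees
(4–8 taxa), the anchor finder against brute force on 500 random pairs up
to 300 bp, OTU binning on 120 synthetic 600-bp profiles constructed as 82
species with satellites, a full-default end-to-end recovery run (6
strains, 48 families, ~200 cluster records), and a complete stitching
round trip at divergence 0 (3 strains × 6 families, every copy split).
These sizes were chosen so each stage's contract is checked exhaustively
at small scale and end-to-end at the default study scale.

## Known limitations

* Fragmented clusters with no intact family exemplar anywhere cannot be
  re-joined; their fragments surface as separate (flagged) records.
* The similarity metric is anchor-based and conservative; above ~8–10%
  pairwise divergence the default thresholds would need to be lowered, or
  the anchor length reduced, and the package is not tuned for that regime.
* Neighbour joining replaces likelihood inference; branch support values
  are not computed.
* No multiple-sequence alignment is performed; distances are strictly
  pairwise, which is what the downstream algorithms require.
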