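---
title: "Methods: overlap-layout-consensus assembly of noisy long reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: overlap-layout-consensus assembly of noisy long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`olca` is a desk-scale overlap-layout-consensus (OLC) assembler for noisy
single-molecule long reads, in the MARVEL/Dazzler tradition: local
alignments of all reads against all reads, organised into per-read piles,
drive both read correction and layout. This vignette explains the model
behind each stage, the tunable parameters and their defaults, the
numerical choices, and what the simulation-based tests do and do not
demonstrate about real data.

## The four phases

1. **Set-up.** Reads are grouped by their ZMW (sequencing well): one
   well can emit several subreads, of which only the longest is kept;
   reads shorter than `min_length` (default 4,000 bases, following the
   published protocol this package reimplements at small scale) are then
   dropped. Plain FASTA names are treated as singleton wells so that
   arbitrary input assembles too.
2. **Read patching.** All-vs-all local alignments of the raw reads are
   computed with repeat-masked seeding; piles are scanned for the
   signatures of four artefact classes (chimeric joins, missed-adapter
   fold-backs, polymerase strand jumps, long low-quality segments);
   breaks split reads and low-quality stretches are replaced with
   partner-derived sequence. A spanning-chain rule additionally excludes
   reads whose repeat regions (up to 8 kb) cannot be certified
   contiguous by at least 3 proper alignment chains.
3. **Assembly.** Patched reads are re-masked and re-aligned; piles are
   filtered to proper dovetail chains; contained reads are set aside;
   the remaining overlaps form a directed string graph on oriented
   reads; transitively implied edges are removed; maximal unbranched
   paths become primary contigs.
4. **Consensus.** Each contig's backbone (path reads trimmed at their
   overlaps) is polished by one deterministic column-majority vote over
   all reads realigned to it.

## Alignment model

Alignments are seeded by exact k-mer matches (`k = 14`) whose start
position lies outside the masked intervals of *both* reads; both strands
of the B-read are tried. Seeds are clustered by diagonal (single-linkage
with a 256-base band), thinned to a co-linear chain (longest increasing
subsequence), and aligned in three parts:

* an **anchored middle**: stretches between seeds that share a diagonal
  and match exactly are copied; other inter-seed gaps get a small banded
  edit-distance DP (full DP below 96 bases, guided band above);
* two **extensions** outward from the outermost seeds, using a
  score-maximising banded DP (match `+max_divergence`, error
  `-(1 - max_divergence)`) with an X-drop of 30 — roughly 66 bases of
  unrelated sequence — so chimeric junctions stop extension quickly;
* the concatenated edit path is trimmed to all maximal segments with
  identity at least `1 - max_divergence` (iterated maximum-scoring
  subsegment extraction), each reported as one local alignment.

The reported `diffs` of every alignment is the **exact** Levenshtein
distance of the reported segments, recomputed with a blocked
bit-parallel algorithm; the banded path only bounds it from above. Unit
tests verify this against `utils::adist` on hundreds of seeded pairs.
Identity is defined as `1 - diffs / max(span_a, span_b)`; B-read
coordinates are always stored on the forward strand with a complement
flag, all intervals 0-based half-open.

Ties in the banded DP are resolved gap-first so that co-optimal paths
push insertions and deletions toward the alignment ends, where the
identity trimming expects them; without this preference, boundary
indels scatter into the matched region and the reported ends ragged by
tens of bases.

### Masks and extension

Masking's purpose is to keep repeat-induced alignments from being
computed at all. Seeding alone cannot do that: an extension entering a
clean masked repeat would happily cross it. Extensions therefore stop
after crossing `mask_extension_limit` (default 500) masked bases.
Consequently: dust and tandem masks (tens to hundreds of bases) are
crossed; masked repeats up to about `max_gap + 2 x 500` bases are
bridged at the chain level; longer masked repeats end the chain inside
the repeat — exactly the "proper chains that prematurely end in repeat
regions" situation — and those read pairs are re-aligned without any
mask (`realign_unmasked`), restoring the full-length overlap.

## Repeat masking tiers

* **Low complexity** (`dust_mask`): windowed triplet-composition score,
  `sum c_t (c_t - 1) / 2` over the 64 triplet types divided by the
  window's triplet count; windows over threshold 2.0 (window 64) are
  masked. Homopolymers and microsatellites score far above this; random
  sequence averages about 0.5.
* **Tandem** (`tandem_mask`): exact k-mer self-matches (k = 8) at
  offsets up to `max_period` (500); matched footprints are merged
  across gaps up to 50 bases, and a merged interval is kept only if it
  is at least `min_span` (100) long *and* at least 60% covered by match
  footprints — the coverage test rejects chance self-matches in random
  sequence.
* **Interspersed repeats** (`coverage_repeat_mask`): reads are split in
  database order into groups of about one genome equivalent
  (`genome_size_estimate`, a required user input — no estimation from
  data is attempted); within each group all reads are aligned
  all-vs-all, and read positions covered by at least `mask_threshold`
  (10) *distinct* other reads are masked. In a 1x group, unique
  sequence is covered about once, while a family with n copies puts
  about n distinct partner reads over every instance, so the threshold
  cleanly separates copy number around 10.

A consequence of counting distinct reads is that the achievable count
saturates at the group's read number: the masking test scenario uses a
150-kb genome (about 25 reads per 1x group with 6-kb reads) so that a
20-copy family can reach ~20 distinct partners. The three tiers are
unioned into the `repeat` track used for seeding suppression,
premature-chain classification, pile filtering and the spanning-chain
rule.

## Patching rules

For each read's pile (using `span_slack` = 100, `min_flank_support` = 3):

* **Chimera**: an interior position that no alignment spans (window
  `span_slack` each side, clipped at read ends) while at least 3
  alignments end on each side. Blunt chimeric joins produce exactly
  this pattern because no partner read matches across the junction.
  Positions inside masked repeats are excluded here and handled by the
  spanning-chain rule instead.
* **Missed adapter / strand jump**: same no-spanning signature, but
  partners align on both sides in opposite orientations; if their
  forward-strand B-intervals coincide (the read folded back onto the
  reverse complement of its own preceding segment) it is an adapter
  break, otherwise a strand jump.
* **Low quality**: an interior interval at least `min_patch_length`
  (400) long that at least 3 partner chains bridge with an internal gap
  while no alignment spans it. The replacement is the
  lowest-divergence bridging partner's gap segment, polished by the
  other bridging partners. Detection rests on the bridging-gap
  signature rather than a divergence threshold: at three times the
  baseline error rate the pairwise divergence exceeds
  `max_divergence`, so alignments break across such segments and a
  covered-but-divergent state does not arise with this aligner. The
  per-segment quality track (mean alignment divergence per 100-base
  segment, sentinel below 2 covering partners) remains available for
  inspection and pile filtering.

Breaks split reads (`<id>.part<i>`); fragments below `min_length` are
discarded; a read excluded by the spanning-chain rule is dropped
entirely. "Spanning" a repeat interval requires 500 flanking bases on
each side (clipped at read ends): a chain merely touching a repeat
cannot certify that the two flanks belong together.

## Layout

Proper dovetail chains become edges of a directed graph on oriented
reads (`+r` / `-r`), with edge length the overhang of the target read
and the reverse-complement twin edge always present. Containments
(partner covers the read end to end within `end_slack` = 25) are
recorded and kept out of the graph. Transitive reduction removes every
edge implied by a two-edge path whose lengths agree within `fuzz`
(200 bases); a brute-force reachability oracle over random consistent
overlap graphs verifies that reachability is preserved. Touring walks
maximal unbranched paths from tips; at junctions the extension with the
most aligned bases wins (then fewer diffs, then smaller read index —
fully deterministic); a walk that returns to its start is flagged
circular. Singleton paths are reported only when nothing was assembled
at all: at usable coverage an unplaced read is contained, repeat-only
or junk.

Consensus realigns every database read to the contig backbone and takes
a per-column majority over base/deletion votes plus between-column
insertion strings (an insertion is applied when a single inserted
string wins an absolute majority of the covering reads). Ties keep the
backbone base. This replaces signal-level polishing (out of scope
here); one pass suffices at the simulated error rates — the noisy
100-kb scenario lands within 0.05% of the true length and the
error-free scenarios are reproduced exactly.

## Circular (mitogenome) mode

`assemble_mito` aligns all reads to a doubled copy of the reference so
chains may wrap the origin, keeps reads with a proper circular chain
(aligned read bases within 4–14 kb and at most 1,500 unaligned bases —
the published filter), patches them, splits them into fragments of
half the reference length overlapping by 1,500 bases (so the circle
cannot close through a single read), assembles, and circularizes: if a
suffix of the contig aligns to a prefix with identity at least 0.95
over at least 500 bases, the duplicate copy is trimmed and the contig
flagged circular. The trim point is `a_begin - b_begin` of the
self-overlap — the circular period — so error-free input recovers the
reference length exactly.

## The simulator

`simulate_genome` plants repeat families (tandem or scattered,
substitution-mutated from a family consensus at `1 - identity` per
base) in uniform random background; `simulate_reads` draws log-normal
read lengths (1st percentile pinned to the minimum, hard-truncated),
samples both strands, wraps the origin on circular genomes, clips at
linear genome edges (start positions range over `[-(L-1), G-1]`, which
keeps terminal bases coverable), and applies indel-dominated errors
(55% insertion / 25% deletion / 20% substitution by default). Injected
artefacts mirror the four patching classes; chimeric joins are blunt.
All randomness flows from one seed; identical seeds give byte-identical
output.

Defaults used across the test scenarios: 10% total error (a
conservative stand-in for raw single-molecule error profiles), repeat
family identity 0.95, coverage 30x for assembly scenarios and 12x for
the masking scenario. What the simulator does **not** model: realistic
per-base quality values, sequence-context-dependent error (homopolymer
run-length bias), chimera hotspots, coverage bias, or heterozygosity —
so passing tests demonstrate algorithmic correctness on the stated
error model, not performance on any particular instrument's data.

## Numerical choices and degenerate inputs

* k = 14 seeds, at least 3 per diagonal band (band 256); sensitivity at
  27% pairwise divergence (two 10%-error reads from 0.95-identity
  repeat copies) is ~1 expected seed per 50 bases, comfortable.
* `max_divergence` 0.30, `min_alignment_length` 600, `end_slack` 25,
  chain `max_gap` 1500: MARVEL-style practice; all exposed in the
  config with provenance flags (`paper` vs `chosen`) so the
  protocol-inherited values (4 kb, 10, 8 kb, 3, 4–14 kb, 1,500) are
  auditable in every run log.
* Alignment-end raggedness is a few bases; every "reaches the read end"
  decision uses `end_slack`.
* Empty inputs: an empty FASTA yields an empty assembly, zero statistics
  and a warning; a genome size estimate above the total read length
  produces a single masking group and a warning; an empty contig set
  gives an all-zero N(x) curve.
* Problem sizes in the test-suite scenarios (100-kb genomes at 30x,
  150 kb at 12x for masking, 15,303-base circular genomes at 40x) are
  the package's chosen desk-scale study conditions: large enough for
  every mechanism (containment, branching, repeat masking, chimera
  support counts) to operate, small enough to be re-run routinely.

## Known limitations

* No haplotype handling: bubbles from heterozygosity are toured through
  by the aligned-bases tie-break, not popped or purged.
* No scaffolding and no signal-level polishing; consensus quality is
  bounded by the column-majority model (~99.5% at 30x / 10% error).
* The aligner is designed for reads up to a few tens of kilobases; no
  trace-point encoding or wavefront guarantees.
* Coverage masking needs a sensible external `genome_size_estimate`;
  a badly wrong estimate shifts the effective per-group coverage and
  with it the meaning of the 10-read threshold.
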