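---
title: "Chromosome binning of low-coverage long reads: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromosome binning of low-coverage long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`chromobin` treats chromosome assignment of reads as label propagation on
an overlap graph. Three sources of evidence are combined:

1. **Reference alignments** give each read an initial label set: the
   chromosomes it aligns to with a block of at least `min_block_len`
   (default 500 bp). Secondary alignments count — a read from a repeat
   shared between chromosomes legitimately carries several labels — and a
   read with no passing alignment is labeled `None`. When a pangenome
   graph is supplied, `None` reads aligned to non-backbone (bubble)
   segments are resolved by a breadth-ordered bidirectional search through
   the pangenome label graph to the nearest backbone (`chr*`) segment;
   conflicting labels at equal distance leave the read unresolved. The
   assumption is that bubble segments cohere with the chromosome whose
   backbone they attach to.

2. **All-vs-all read alignments** define weighted edges. The weight is the
   overlap degree `od = (al/ql)(al/rl)(m/al)w`: the product of the two
   overlap fractions and the match fraction, scaled by `w`. Two reads that
   overlap end-to-end with few mismatches approach `w`; short or partial
   or noisy overlaps score low. Containments (alignment covering at least
   `containment_cov` = 0.95 of the shorter read) collapse the shorter read
   into the longer; collapsed reads donate their labels and later inherit
   their representative's final class.

3. **Split alignments** reveal translocations between sample and
   reference. Adjacent split segments of one read on different
   chromosomes, within 100 bp of each other on the read, are canonicalized
   into breakpoint signals (eight chromosome-order × strand cases, output
   always lexicographically ordered), greedily clustered within `TH_BND`
   (default 1000 bp) on both coordinates, and clusters below `min_support`
   (default 3) are dropped. A translocation produces two junctions that
   share the acceptor coordinate, so when the per-side positions of the
   surviving clusters are re-clustered, the side merged from two clusters
   is the insertion breakpoint; its supporting reads become enhanced
   nodes.

The corrector then runs `M` (default 5) randomized iterations. In each,
nodes are visited in a fresh random order; every still-unvisited node
seeds a greedy bidirectional path that always extends along the
highest-weight admissible edge and stops at a significant weight drop,
`w_next <= theta * w_prev + epsilon` (defaults theta = 0.5, epsilon =
0.05 in units of `w`; the rule is boundary-inclusive and never applied to
a path's first step, which has no previous edge). A path longer than
`SN_min` (default 3) overwrites its members with its majority label
(multi-label nodes vote once per label; `None` never outvotes a concrete
label); a path containing enhanced nodes adopts their class outright; a
short path leaves each node its own single-label reading, resolving
multi-label sets to the lexicographically smallest member. The final
class is the per-node majority over the `M` iterations, ignoring `None`
unless unanimous. Every tie in the whole procedure — edge priority, path
vote, consensus — breaks lexicographically, which together with a single
seeded RNG stream makes a run exactly reproducible; re-running with the
same configuration yields a byte-identical `assignments.tsv`.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `w` | 1 | — | overlap-degree scale; search is scale-covariant when `epsilon` scales with it |
| `min_block_len` | 500 | bp | edge/class admission; rejects alignment chatter |
| `containment_cov` | 0.95 | fraction | containment declaration threshold |
| `theta`, `epsilon` | 0.5, 0.05 | —, w-units | drop-rule truncation of path growth |
| `SN_min` | 3 | nodes | minimum path support for majority overwrite |
| `M` | 5 | iterations | consensus depth |
| `max_read_gap` | 100 | bp | split-segment adjacency on the read |
| `TH_BND` | 1000 | bp | breakpoint cluster radius |
| `min_support` | 3 | reads | breakpoint cluster survival (sized for ~5×) |

All are exposed on `pipeline_config()` and the `chromobin run` command
line.

## What the synthetic data emulates — and what it does not

`simulate_genome()` builds independent random chromosomes (default 3 ×
200 kb) with an optional shared repeat family and an optional planted
translocation; `simulate_reads()` samples ~10 kb truncated-normal reads to
5× with known chromosome of origin, half reverse-complemented;
`naive_align()` is an exact k-mer (k = 21) seed-and-extend aligner that
chains seeds by diagonal, counts interior mismatches, emits secondary
records for repeat multi-mappings and splits records at rearrangement
junctions. The test problem sizes (300 reads, ~600 kb genome) keep the
whole suite and the acceptance script in the minutes range on one core.

Planted repeat copies diverge from their master sequence by 1%
substitutions per copy (`repeat_divergence`): identical copies would make
the chromosome of origin of repeat-interior reads unrecoverable in
principle, and real repeat families are never identical. This is a
deliberately hard setting — at ~2% pairwise divergence the overlap-degree
difference between same-copy and cross-copy read overlaps is smaller than
the variation due to overlap length, so greedy paths can cross between
repeat copies when the repeat is longer than the reads (15 kb vs 10 kb).
Reads lying wholly inside such a repeat may then be carried to another
chromosome by their path's majority; this is a real limit of
overlap-degree-guided path search at this scale, visible in the repeat
fixture's accuracy numbers computed by the test suite, not a property of
real centromere-scale data that the fixture can claim to measure.

Other simplifications: substitution errors only (no indels — the aligner
relies on this to chain by diagonal), no diploidy or haplotype structure,
uniform coverage, and a read-length floor of 200 bp. Error-free reads make
alignment endpoints exact, which the translocation tests exploit; real
HiFi data has ~0.1–1% error and minimap2 handles it.

## Numerical and design choices

* **Coordinates** are 0-based half-open everywhere (PAF/GAF/BED
  convention); sequences are handled 1-based only internally.
* **Overlap-degree form**: computed as `al*m*w/(ql*rl)`, algebraically
  identical to the factored form but exact at `al = 0` (degenerate
  alignments score 0).
* **Secondary alignments** are parsed and kept (`tp:A` tag; absent means
  primary); filtering is the graph builder's policy, because suboptimal
  alignments carry the repeat-ambiguity information the corrector needs.
* **Edge deduplication** keeps the maximum weight per node pair; every
  forward edge has a reverse partner of identical weight, asserted as a
  graph invariant.
* **Containment ties** (equal lengths, mutual coverage) collapse the
  lexicographically smaller id, so the collapse is deterministic;
  transitive chains resolve by union-find to the longest survivor.
* **Pangenome search** is breadth-ordered rather than depth-first: a DFS
  answer depends on unspecified neighbor ordering, while nearest-label is
  deterministic and captures the "stop at the first backbone label"
  intent. Equal-distance conflicts return no label; traversal is capped at
  `max_visits` (default 10⁴) nodes.
* **Split-signal gap** uses |gap| < 100 bp, so a few bases of junction
  micro-homology (slightly negative gap) still pair, while near-complete
  multi-mappings of the same read stretch (strongly negative gap) do not.
  Split segments shorter than `min_seg_len` (= `min_block_len`) are
  ignored, making the support set exactly the junction-spanning reads on
  error-free data.
* **Acceptor orientation**: when only one junction cluster survives (low
  coverage can leave the second junction under `min_support`), the
  insertion side falls back to the chromosome with more aligned bases in
  the cluster — a weak heuristic, flagged here deliberately: with a single
  junction the data do not determine the acceptor.
* **Short paths mark their nodes visited** within an iteration even when
  below `SN_min`, guaranteeing termination and exactly one decision per
  node per iteration.
* **Interval metrics** measure coverage by the union of overlapping
  intervals, strictly greater than the threshold on both sides; recall is
  counted truth-side, which makes swapping query and truth exchange
  precision and recall exactly.

## Known limitations

* Repeat families longer than the read length at low coverage can defeat
  the path majority (see above); the unassigned-rate and accuracy split in
  `binning_accuracy()` keeps the two failure modes distinguishable.
* Only inter-chromosomal translocations are detected; inversions,
  duplications and intra-chromosomal events are out of scope, as is
  general SV calling.
* The naive aligner is an oracle for synthetic, substitution-only data —
  it is not a replacement for minimap2/minigraph on real reads.
* Pipeline stages run sequentially; the contract for any future
  parallelism is bit-identical results to the sequential run with the
  same seed.
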