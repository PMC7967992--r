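---
title: "Methods: alignment normalisation, chimera detection, and diagram layout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: alignment normalisation, chimera detection, and diagram layout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alnspect)
```

## The problem

Long sequencing reads (nanopore in particular) are occasionally chimeric:
two unrelated molecules joined into one read, either by ligation during
library preparation or *in silico* when the basecaller merges two molecules
that transited a pore in quick succession. An assembler that trusts a
chimeric read may weld two loci together, so identifying and splitting such
reads before assembly can improve contiguity without hurting correctness.
Given alignments of reads (or contigs) against a reference, a chimera has a
distinctive geometric signature — two substantial, disjoint alignments to
unrelated places — and that signature is what this package detects. The
same alignment sets support four diagram types for visual assessment of
assemblies and coverage.

## One coordinate convention

Every parser converts to a single internal convention before anything else
happens: 0-based, half-open intervals `[start, end)`, with query
coordinates always expressed on the forward strand of the query and a
separate strand flag. PAF and PSL are already in this convention; SAM,
BLAST tabular and MUMmer coordinates are 1-based inclusive and converted on
ingest; BLAST and MUMmer report reverse alignments as descending intervals,
which are normalised ascending with `strand = "-"`. Doing this once, at the
boundary, removes an entire class of off-by-one and strand-frame bugs from
everything downstream, and it is why one chimera rule and one layout engine
can serve five input formats.

Two formats cannot fill every field and are flagged rather than guessed at:

* BLAST tabular without a `qlen` column has no query length; it is
  approximated by the maximum `qend` observed for that query anywhere in
  the file, a lower bound. The parsed set carries an
  `approximate_query_length` attribute and a warning, because chimera
  coverage fractions computed against an underestimated length are
  overestimates.
* MUMmer `show-tiling` rows carry no query interval at all; it is set to
  `[0, contig_length)` and flagged `approximate_query_interval`.

For SAM, the query interval and total query length are reconstructed from
the CIGAR string: clips (soft *or* hard) define the offsets and count
toward the query length, so the records of one split read agree on their
query length even when some are hard-clipped. Reverse-strand records are
reflected into the forward query frame (`start' = L - end`). Secondary
alignments (flag 0x100) are skipped — they re-describe a locus that the
primary already covers and would double-count — while supplementary
alignments (0x800) are kept, since a chimeric read manifests exactly as a
primary plus a supplementary record.

## The noise filter

Long-read aligners emit many short spurious hits. Before any analysis, an
alignment is dropped when its query span is below a fraction of the query
length; the default is 1%. The filter runs before chimera detection, so a
read with two real alignments plus a handful of sub-1% hits is still
detected (the "exactly two" rule below counts surviving alignments). The
operation is idempotent and order-preserving.

## The chimera rule

A query is called chimeric iff, after filtering:

1. it has **exactly two** alignments;
2. their query intervals are disjoint (intersection of length zero;
   abutting intervals qualify);
3. if both alignments hit the same target, their target intervals are also
   disjoint — the two pieces must come from different sections of it;
4. the two query spans sum to at least `min_total_coverage` (default 0.90)
   of the query length;
5. each span is at least `min_each_fraction` (default 0.10) of the query
   length.

The reported join position is the floor of the midpoint of the unaligned
gap, `floor((left_end + right_start)/2)`, in query coordinates. The
parameter invariants `0 < min_each_fraction <= 0.5` and
`2·min_each_fraction <= min_total_coverage <= 1` make the rule internally
consistent (two pieces of at least the per-piece minimum must be able to
reach the joint minimum).

Decisions where the rule's plain statement left room:

* **"Exactly two" is literal.** A query with three surviving alignments is
  never called, even when two dominate. The 1% filter does most of the work
  of discarding trivial extras; anything that survives it is treated as
  evidence of a more complex structure than a simple two-part chimera.
* **Overlap means intersection length > 0.** Abutting alignments
  (`[0,500)` and `[500,1000)`) are non-overlapping and give a join exactly
  at the shared boundary.
* **Same-target calls are reported, not suppressed.** A read aligning to
  the two ends of a circular reference (chloroplast, mitochondrion)
  satisfies the rule but is an artefact of linearising a circle. Rather
  than hard-coding that exception, `detect_chimeras(exclude_targets=...)`
  lets the user name circular references on which same-target calls are
  dropped; the default reports everything.
* **Monotonicity.** Raising either threshold can only shrink the call set;
  this is property-tested and gives users a predictable dial.

## Read splitting

Each called read is replaced in place by its prefix `[0, join)` and suffix
`[join, length)`, named `<read>_left` / `<read>_right`; FASTQ qualities are
subset in register; every other read passes through byte-identical. Total
base count is conserved by construction. A call whose read is absent from
the file is skipped with a warning (the alignment file and read file may
legitimately differ); a join on or outside a read's boundary is an error,
because it would produce an empty fragment.

## Coverage

A target is divided into fixed-width bins; each alignment increments every
bin its target interval intersects by at least one base (any-overlap, no
fractional weighting). Before binning, each query's overlapping alignments
are deduplicated: sort by target span, largest first, ties broken by input
order, and greedily accept whatever does not overlap an accepted alignment
on the same target. Counts therefore approximate "how many query sequences
cover this bin" rather than "how many alignment records". At bin size 1 the
bin sums equal the aligned base count of the deduplicated set exactly — the
conservation property the tests and the acceptance script check.

Two presentations share this machinery:

* **Coverage map** — each target binned into the same *number* of bins
  (default 10,000 for the square form, 1,000 for the long bar), so every
  heat map has the same size and bin width varies with target length.
* **Genome coverage** — all targets binned at one shared bin *size*,
  `ceiling(total_length / total_bins)` (default budget 1,000 bins), drawn
  contiguously in order, so one image shows all chromosomes at a common
  scale. Per-target `ceiling` rounding can add a few bins over the budget;
  exactness of the budget was judged less important than exact per-target
  bin arithmetic.

Target order defaults to order of first appearance in the input, and can be
overridden with an explicit `target_order` when chromosome order matters.

## Diagram layout and rendering

Layouts emit backend-neutral draw commands (rectangle, line, text, polygon,
each with a semantic `role`), and two renderers turn command lists into
documents: SVG, and standalone TikZ for LaTeX workflows. Both are
byte-deterministic for a fixed command list, which makes "same inputs, same
bytes" a testable contract of the command-line tool. The geometry lives on
an abstract canvas 1040 units wide (1000 drawable plus margins), scaled by
sequence length.

* **Alignment diagram** (per target): the target is a red bar; each
  alignment a rectangle at its target interval, rows ordered by query name
  then target start; a line through each rectangle shows the full query
  extent at the alignment's bp-per-unit scale, so a small alignment of a
  huge query visibly overhangs. Overhangs beyond the canvas are clipped
  with an arrow marker.
* **Contig alignment diagram** (per query): an outlined rectangle scaled to
  the query; inside it, up to the ten longest alignments (query span, ties
  by input order), filled with a colour keyed to the target (12-colour
  palette by order of first appearance, recycled) and shaded by a linear
  gradient encoding target position and orientation — light end at the
  lower target coordinate, so forward alignments run light→dark
  left-to-right and reverse alignments the opposite way. Chimeric queries
  get a red `C`; with `chimeras_only` the other queries are omitted and the
  `C` suppressed (it would be redundant).
* **Coverage map**: one cell per bin on a white→red scale normalised to the
  track maximum (an all-zero track renders white; no division by zero).
  The square form wraps row-major into an `n×n` grid, `n = ceiling(sqrt(bins))`.
* **Genome coverage**: one constant-size cell per bin, all targets in
  order, jointly normalised, labelled per target.

The exact visual constants (palette, fonts, margins) are this package's
own; diagrams are specified and tested structurally, by an exact census of
primitives per role, not pixel-wise.

## The synthetic-data generator

`generate_fixture()` emulates the reference-guided long-read setting the
detector targets: uniform-random references (defaults: 3 targets of
30–60 kb; 200 reads of 1–5 kb; 10% chimeric; seed-deterministic). An
ordinary read is one segment of one reference (forward or reverse
complemented) with a single alignment covering all but up to 2% at each
end. A chimeric read is `seg1 + seg2` from two distinct references, with
the true breakpoint recorded as truth; its two alignments are trimmed back
0.1–2% of the read length on each side of the junction, because a real
aligner cannot anchor an alignment right up against a chimeric breakpoint.
The split point of each side is drawn so each piece is at least 20% of the
read, leaving ≥18% after trimming and ≥96% joint coverage — comfortably
inside the default thresholds, so recovery of every planted chimera is a
correctness requirement, not a statistical hope. Optionally, reads gain one
spurious alignment strictly shorter than 1% of the read, which the default
filter must remove.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: sequencing error and the ragged alignment
boundaries it causes (alignments are written from true provenance, not
recomputed by an aligner), repeat-induced multi-mappings, chimeras of more
than two pieces, reads spanning circular-origin junctions, and biased
coverage. On real data the rule's precision depends on the aligner's
behaviour around repeats, and reads whose two pieces overlap on the query
(ambiguous case 2 above) are deliberately left uncalled.

## Problem sizes and numerical choices

The test suite checks the detector against an independent per-base
brute-force oracle on 1,200 random query geometries, recovers planted
chimeras from a 5,000-read fixture (recall and precision both required to
be 100%, every join inside its read's unaligned gap), and verifies
coverage/splitting conservation and rendering determinism on smaller
fixtures; the full suite runs in about a minute. All quantities are exact
integer arithmetic on base-pair coordinates — there are no tolerances
anywhere in the pipeline; equality assertions are exact. Ties are broken by
input order (dedup) or by query-name sort (call output) so that every
result is deterministic given the input file.

## Known limitations

* BLAST input without `qlen` and `.tiling` input yield approximate query
  geometry; chimera calls on such input inherit that approximation.
* The fixed-width `show-coords` pretty format (without `-T`) is not
  parsed; request the tab-delimited dialect with `show-coords -l -T`.
* BAM/CRAM are out of scope; convert to SAM text first.
* The contig alignment diagram draws every query in one column; for very
  large query sets the practical entry point is `chimeras_only` or
  pre-filtering to queries of interest.
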