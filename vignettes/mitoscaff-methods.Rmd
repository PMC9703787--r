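---
title: "Reconstructing multipartite plant mitogenomes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing multipartite plant mitogenomes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Plant mitochondrial genomes (mitogenomes) rarely exist as a single circular
chromosome. They are better described as a dynamic population of linear and
circular molecules built from a shared set of unique segments and
interspersed repeated elements (REs); recombination at the repeats generates
alternative arrangements (isoforms), some present at substoichiometric
levels. A short-read assembly of such a genome collapses each repeat family
into one contig and truncates contigs at repeat boundaries, so the
assembly's structure must be recovered afterwards: which contigs are
mitochondrial, how many genomic copies each represents, how they connect,
and which scaffolds close into circles.

`mitoscaff` implements that reconstruction as a tested pipeline:

1. **Selection** of mitochondrial contigs from a whole-genome short-read
   assembly, by gene content and by depth of coverage.
2. **Copy classification** of the selected contigs relative to the median
   coverage.
3. **Seed-and-extend scaffolding** with long reads as framework, with
   multi-placement of repeat contigs, an ambiguity stop rule,
   alternative-connection reporting, and circularity detection.
4. **Polishing** of read-derived junction sequence with short reads, using
   the chloroplast genome as a mapping decoy.
5. **Repeat and MTPT statistics** (interspersed repeat families,
   plastome-derived insertions) and **copy-number estimation**.

A ground-truthed simulator of multipartite mitogenomes makes every stage
testable without external data.

# Contig selection and copy classes

Two criteria select mitochondrial contigs. Criterion 1 keeps any contig
with a mitochondrial gene hit (CDS, rRNA or tRNA), regardless of length or
coverage; the hits arrive as an input table, because producing them is a
database search, not a property of the assembly. Criterion 2 keeps contigs
of at least 2,000 bp whose mean short-read coverage falls inside the range
spanned by the criterion-1 contigs; in the motivating study that derived
range was 32–139x. Boundaries are inclusive — the criterion text does not
say how exact ties were treated, and inclusion is the only choice that
keeps criterion 2 a superset-preserving relaxation of criterion 1's range.
An explicit `cov_range` can be supplied when no gene-hit table is
available.

Copy classes are assigned from the ratio of each contig's coverage to the
median coverage of the selected set. The original analysis describes the
partition verbally (a low class around 0.36–0.8x of the median, a single
class near the median, and repeat-like contigs at 1.4–2.3x including
"double" and "intermediate" coverages). `mitoscaff` fixes that verbal
partition with three constants, all exposed as parameters:

* `low_max = 0.80` — below this ratio a contig is `low`
  (substoichiometric);
* `single_max = 1.25` — up to here a contig is `single`;
* `mult_tol = 0.15` — a ratio within 0.15 of an integer k ≥ 2 is
  `multiple(k)`; otherwise the contig is `intermediate(k, k+1)` for the
  bracketing integers.

Any contig at or above `single_max` is flagged *repeat-like* and becomes
eligible for placement in more than one scaffold. With the defaults, 89x at
median 89 is `single`, 178x is `multiple(2)`, and 204x is
`intermediate(2,3)` — the verbal classes of the motivating data.

# Scaffolding

## Evidence collection

Long reads of at least `min_read_len` (default 10 kb) are aligned to all
contigs with BlastN — the aligner the original manual procedure used — keeping
hits at `min_identity` (default 0.90) or better. Fragmented local hits of
one read against one contig are merged when collinear; hits nested inside
another hit's read interval are dropped. On each read the surviving hits,
ordered by read position, form a chain; every adjacent pair in a chain is
junction evidence, provided that:

* the gap or overlap between the two contig projections on the read is at
  most `max_junction_gap` (1 kb), rejecting chimeric joins;
* each hit reaches the contig end that faces the junction (within
  `end_slop`, 50 bp);
* at least one of the two hits is a *strong anchor*: it covers its whole
  contig, or at least `min(min_end_overlap, 0.9 × contig length)`
  terminating at the facing end. The 10-kb end-overlap rule is undefined
  for contigs shorter than 10 kb, so it is scaled to 90% of the contig —
  preserving the intent (near-complete anchoring) at any contig size.

Support for a connection is the number of distinct reads providing it; a
connection is used only at `min_support` (default 3) or more reads.
Orientation conflicts among a junction's reads are resolved by majority
vote (ties toward "+") — a choice the manual procedure left unrecorded.

## Extension, repeats, ambiguity

Seeds are processed in descending length order among unused non-repeat
contigs; repeat-like contigs cannot seed a scaffold, since the procedure is
anchored on the largest *unique* contigs and repeat contigs are described
only as multi-placed. Extension from a scaffold end accepts a connection
when it is supported and either (a) it is the only qualifying partner, or
(b) the top partner is repeat-like. A non-repeat end with two or more
qualifying partners stops extension; the alternatives go to the adjacency
report. Extension *through* a repeat-like contig continues only when the
far side is unambiguous: reads that span flank–repeat–flank phase the
crossing (the same-read triple determines which exit belongs to which
entry), and when no spanning read exists, a unique far-side partner is
required. This is the algorithmic codification of the manual stop rule:
extension halted whenever the reads disagreed about the adjacent contig,
which happens chiefly at repeat contigs.

Non-repeat contigs appear in exactly one scaffold; repeat-like contigs may
appear in several, and unplaced contigs become singleton scaffolds. A
repeat with two distinct flanking pairs (A–R–B and C–R–D) is therefore
placed twice and its adjacency report lists four partners — the pattern
observed for the highest-coverage contig of the motivating study, where PCR
confirmed four alternative connections.

## Circularity and junction filling

A scaffold is flagged circular when at least `min_support` reads link its
two terminal ends in consistent orientation (a single contig can
self-circularize). A cycle that closes *through* a repeat leaves the same
repeat-like contig at both termini in the same orientation; the trailing
copy is then emitted once and the scaffold flagged circular, since the wrap
junction is exactly the evidence that placed it.

Junction sequence between adjacent placements is taken from the longest
spanning read (`best_read`). The read is oriented to the scaffold, the
contig ends are projected onto it (extrapolating across any unaligned
contig tail), and the inter-contig read interval is inserted; when the
projections overlap, the duplicated bases are trimmed once from the
incoming contig. Scaffold sequences therefore never contain N — gaps are
filled with real read sequence and polished afterwards. Best-hit ties in
all alignment steps break deterministically by (higher identity, longer
alignment, lexicographic contig id).

# Polishing

Short-read mapping follows a CLC-style contract: a read counts only where
it aligns over at least `length_fraction` (0.9) of its length at
`similarity` identity or better, and only at its single best location —
reads with equal best scores at two or more loci are discarded as
ambiguous, which keeps repeat copies from contaminating each other's
consensus. The mapper is a k-mer seeded (k = 15) banded aligner (band
half-width 20 bp); it aligns the entire read, so placements whose read
overhangs the reference boundary (including reads spanning the origin of a
circularized scaffold) are rejected rather than soft-clipped.

Consensus extraction takes the majority base where depth reaches the
low-coverage threshold (default 5); ties resolve to the reference base, and
below-threshold positions keep the reference base and are reported as
low-coverage intervals (an `"n"` mode exists for the alternative
convention, but reference fill is the default because the final scaffolds
of the motivating assembly contain no N). Majority deletions are removed
and an insertion is applied when its most frequent sequence is seen in more
than half of the covering reads.

Polishing runs the mapping/consensus cycle at similarity 0.90 (pass 1),
then repeats at 0.95 until the sequences stop changing. Because consensus
is computed genome-wide, the read-derived junction spans and the final
whole-scaffold polish coincide in one pass. Circular scaffolds get one
extra treatment: reads spanning the circular origin cannot map onto a
linear representation, leaving the terminal read-length under-covered, so
circular scaffolds are rotated by half their length and re-polished. When
that origin pass changes nothing the unrotated sequence is returned
(already-perfect scaffolds are a fixed point); otherwise the corrected
sequence is reported at the rotated origin, which is immaterial for a
circular molecule. Within repeat copies that occur in several scaffolds,
short reads are ambiguous and are dropped; those interiors are
contig-derived (already exact to the assembly) and appear in the
low-coverage report rather than being force-called.

# Repeats and MTPTs

Interspersed repeats are enumerated exactly: all maximal repeated
substrings of length `min_len` or more occurring at least twice across the
sequence set, on both strands, via a suffix array with LCP intervals
(right-maximality) and BWT character diversity (left-maximality). Exact
matching is the default because the reference procedure (near-exact BLAST
self-comparison) operates at near-identity and exactness admits an
unambiguous brute-force oracle, which the test suite exercises against a
maximal-pair enumeration on hundreds of random and planted sequences. A
repeat and its reverse complement form one family (strand recorded);
palindromic self-hits are counted once. Runs of directly adjacent copies
(gap ≤ `tandem_gap`, default 0) collapse as tandem; families left with
fewer than two interspersed placements are excluded, as the RE statistics
concern non-tandem repeats.

The RE proportion is total RE length over sequence length. The reference
tool's binned output does not state its total-length accounting, so three
modes are provided and the choice is explicit: `union` (default; length of
the union of all copy intervals — the only mode guaranteed to stay in
[0, 1]), `family_sum` (one unit length per family), and `all_copies` (unit
length × copy number). The two reporting tiers used in the field (all REs
≥ 24 bp; interspersed REs ≥ 50 bp with mean size, mean copy number and a
size histogram binned 50–200, 200–1k, 1k–10k, > 10k bp) are both exposed.

MTPTs (plastome-derived insertions) are found by BlastN of the chloroplast
genome against the mitochondrial sequences, keeping hits longer than 50 bp
with identity above 90% (both bounds exclusive, as the criteria are stated
as "above"/"more than"). Mito-side hits overlapping or within 10 bp are
merged into one distinct region; the merge radius is a package choice — the
reference reports merged regions without stating its rule — and 10 bp only
joins hits split by alignment micro-breaks, not biologically separate
insertions.

# Copy number and cross-genome comparison

The cellular copy number of the mitogenome in a (haploid) tissue sample is

```
copies per cell = mean mitogenome coverage / (input bases / haploid genome size)
```

reported raw and rounded to two significant figures (the headline value is
an order-of-magnitude statement). The mean mitogenome coverage is an input
number, not recomputed, because the upstream mapping that produced it may
differ in contract from the per-contig coverages. The cross-genome
analysis runs the repeat finder on each genome and correlates RE
proportion with genome size (Pearson r, p from the t transform with n − 2
df); with the handful of sequenced gymnosperm mitogenomes available, the p
value is reported but r is the meaningful anchor.

# The simulator

`simulate_mitogenome()` draws unique segments and repeat families at a
target GC of 0.46 (the observed mitogenome GC), arranges them into circular
and linear molecules with per-molecule stoichiometry, and records the full
ground truth: molecule sequences, the junction table, repeat placements,
expected relative coverage per element, and planted MTPT coordinates in
both coordinate systems. Repeat unit lengths follow the observed mixture —
bulk 50–200 bp plus a rare heavy tail reaching 10 kb and more — via
`repeat_len_mixture`; structural tests override it to mid-size (4–8 kb)
families so the repeats surface as selectable contigs, which is the regime
where multi-placement matters. Repeat copies are planted verbatim
(near-identity is what the exact repeat finder context implies); a per-copy
divergence knob exists for stress tests. Alternative junctions arise by
placing one family between different unique-segment pairs in different
molecules.

`fragment_to_contigs()` emulates the short-read assembler's outcome rather
than the assembler itself: one contig per unique segment, one collapsed
contig per repeat family, coverage = base depth × expected relative copy
number with multiplicative Gaussian noise (default CV 5%), and truth-label
gene hits standing in for the BLAST-based gene search. Long reads are
log-normal (mean 14 kb, the reported PacBio mean; truncated to [1 kb,
molecule length]) with configurable error split 50% substitutions / 25%
insertions / 25% deletions; circular molecules emit origin-spanning reads.
Short reads are 2 × 150 bp pairs with Gaussian inserts (400 ± 40 bp).

When a test states junction-level read depth as a precondition (the
recovery properties assume every junction is spanned by at least three
anchoring reads), `min_junction_depth` makes the sampler enforce it:
junctions left under-covered by the random draw receive deterministic
top-up reads carrying a full scaffolding anchor. This realizes the stated
study condition rather than leaving it to sampling luck at modest depth.

What the simulator does *not* emulate — and hence what passing tests do not
show about real data: realistic PacBio error profiles (chimeras, adapter
artifacts, length-quality correlation), nuclear background reads and
nuclear-repeat contamination, diverged repeat copies, assembler
misassemblies, and base-composition biases. Recovery results on synthetic
genomes certify the reconstruction logic, not robustness to dirty inputs.

Default test scale is a 100–300 kb genome (not the 1.43 Mb of the real
assembly) across two molecules, with 15x long reads and 30x short reads, so
the full suite runs in minutes on one CPU; all thresholds scale through the
configuration. The acceptance checks use twenty seeded genomes of 5–15
unique segments and 1–3 repeat families at that scale.

# Numerical and engineering choices

* **Coordinates.** Internal coordinates are 1-based closed — the native
  convention of R, IRanges and Biostrings, and the one the string functions
  use — while emitted BED files are converted to 0-based half-open per the
  standard. Keeping the host language's convention internally avoids a
  class of off-by-one translation bugs at every `substr()`.
* **Alignment back-ends.** BlastN (the field's and the original procedure's
  tool) performs long-read and plastome alignment through a thin wrapper;
  `Biostrings::pairwiseAlignment` serves as an independent quadratic-DP
  oracle in tests and is never on the implementation path. The short-read
  mapper and the suffix-array repeat finder are implemented in C++ (Rcpp)
  because no installed package exposes those primitives under the required
  contracts.
* **Determinism.** Every generator seeds the RNG from the configuration
  (stage-offset seeds), so a configuration is bit-reproducible; the
  pipeline manifest records md5 checksums and identical config + seed give
  identical checksums. Tie-breaks (best hits, consensus ties, orientation
  votes, family ordering) are all deterministic.
* **Degenerate inputs.** Selection without any gene-hit contig is an error
  naming the remedy (explicit `cov_range`); copy classification needs at
  least three selected contigs and a nonzero median; junction filling
  without a spanning read is an error (unreachable under the build rules);
  an empty long-read set degrades to singleton scaffolds.

# Known limitations

* Scaffolding decisions are greedy per seed; there is no global
  optimization over the junction graph, matching the stepwise manual
  procedure rather than improving on it.
* Isoform stoichiometry is modelled by a free per-molecule multiplier and
  not estimated from data; substoichiometric detection is out of scope.
* The exact-match repeat finder will split diverged repeat copies into
  separate families; the alignment-based tier of repeat analysis is not
  implemented beyond the BLAST-based MTPT detector.
* The short-read mapper rejects reads overhanging reference boundaries
  instead of soft-clipping, slightly depressing coverage within one read
  length of linear scaffold ends; the circular-origin re-polish removes
  the one case where this affects results.
* Accession-scale reproduction of the published *Abies alba* statistics
  requires downloading the deposited scaffolds, chloroplast genome and
  supplementary tables; the corresponding test documents the expected file
  layout and fails informatively when the data are absent.
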