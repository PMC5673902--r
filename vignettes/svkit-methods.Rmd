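---
title: "Methods: split-read SV calling, phasing and reconstruction in svkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: split-read SV calling, phasing and reconstruction in svkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

svkit detects structural variants (SVs) from noisy long reads — nanopore
reads in particular — by clustering split-read alignments, genotypes and
filters the resulting calls, assigns them a parental haplotype from phased
SNVs, and reconstructs long-range rearrangement structure. This vignette
explains the underlying models, the tunable parameters, and the design
decisions taken where the design was genuinely open. The companion
simulator used throughout the test suite is described at the end, together
with what passing its benchmarks does and does not establish about real
data.

## The split-read model

A long read crossing a rearrangement junction aligns as two (or more)
segments mapping to different loci. Internally each aligned segment is the
tuple *x = (c, s, e, k)* — chromosome, 0-based half-open reference
interval, strand — plus read-offset coordinates in the originally
sequenced orientation, mapping quality and percent identity (PID, identical
bases over aligned columns). A read is an alternation of alignment gaps
and segments `[u1, x1, u2, ..., xN, uN+1]`; segments below the mapping
quality threshold `q1` (default 20) are folded into the surrounding gap
rather than deleted, so gap sizes always complement the retained segment
spans to the full read length.

Two practical ingest details are our own choices. Split alignments are
accepted both as separate primary/supplementary records and as `SA`-tag
entries, with duplicates (identical read intervals) collapsed toward the
higher mapping quality. Overlapping read-offset intervals between two
segments of one read — splits some aligners emit — are resolved by
trimming the lower-mapq segment (ties toward lower PID) rather than
discarding the read, because such splits still carry junction signal.

## Junctions, orientation and clustering

Every pair of consecutive segments in a read defines a candidate
breakpoint junction carrying the intervening gap size |u|. Each junction
side is a *breakend*: a coordinate plus an orientation, `+` when the joined
sequence ends at that coordinate (the junction leaves the locus at its 3'
side) and `-` when it starts there (5' side). Under this convention the
side coordinate is always the segment end minus one for `+` and the
segment start for `-`, on both sides, and the orientation pair maps
directly onto SV types: 3'–5' (`+/-`) is deletion/insertion-like, 5'–3'
(`-/+`) tandem-duplication-like, 3'–3' and 5'–5' are the two inversion
junctions. Reverse-complementing the evidencing read leaves breakends
unchanged up to a side swap, so canonicalization — ordering the two sides
by chromosome rank and coordinate — is a pure swap and is idempotent. The
default chromosome order is the human natural order (1..22, X, Y, MT, then
others lexicographically); a configurable list overrides it.

Junctions are clustered when they agree on chromosomes and orientations on
both sides and their side coordinates lie within `d` bp (default 10) on
each side. The literature describes this as recursive merging; we compute
the connected components of the pairwise relation, which is its
order-independent fixpoint — the test suite checks equality with an
explicit quadratic transitive-closure oracle and invariance under input
permutation. Each cluster becomes a candidate SV
*b = (c1, c2, p1, p2, k1, k2, g)* whose positions and gap are member
medians; for even-sized clusters the lower-middle element is taken so that
coordinates stay integral and deterministic. Confidence intervals span the
member minima and maxima. An insertion is called when the median gap *g*
exceeds the reference span *l = |p1 − p2|*, a deletion when *g ≤ l*. When
the 5'–3' orientation (duplication-type) co-occurs with *g > l* the
orientation wins and a duplication is reported; the alternative reading
(insertion) has no support in the junction geometry. Candidates supported
by fewer than `min_support` distinct reads (default 2, comparison `>=`,
strictness configurable) are suppressed.

## Genotyping, reference reads and flags

Reads support the reference allele of a call when one of their segments
crosses a breakpoint end with strictly more than `flank` bp (default 100)
on *both* sides of that end; reads supporting the junction are excluded,
all others ignored. The printed description of this rule in the source
literature mixes a conjunction at one end with a disjunction at the other;
the disjunction admits reads arbitrarily far from the breakpoint, so we
apply the conjunctive form symmetrically at both ends and note the
deviation here.

Genotypes come from a binomial likelihood with a flat prior:
`L(g) = C(A+R, A) p_g^A (1 - p_g)^R` over hom-ref/het/hom-alt. The
allele-support probabilities default to `(0.001, 0.5, 0.9)`, the
split-read parameterization used by the SVTyper genotyper that this scheme
follows. We initially considered `(0.05, 0.5, 0.95)`; that choice turns
out to misbehave under the two-end reference-counting above: a balanced
heterozygous SV has an expected alt fraction near 1/3 (reference reads are
counted at both breakpoints, alt reads once), and with `p_homref = 0.05`
any call whose alt support dips below roughly 0.28× the reference count is
classified `0/0` and then discarded by the hom-ref drop — systematically
deleting genuine heterozygous junctions at moderate coverage. With
`p_homref = 0.001` the hom-ref class only captures calls with essentially
no residual support, which is the intended behavior of the drop. `GQ` is
`-10 log10(1 - posterior)` capped at 99; zero informative reads give
`./.`.

Two annotations follow. `MapQual` (a FILTER entry) marks calls whose
median supporting mapping quality does not exceed `q2` (default 80) — the
call is still reported. The `Cluster` INFO flag marks calls in SV-dense
regions: any sliding window of `cluster_window` bp (default 1000)
containing breakpoints of at least `cluster_min` (default 3) distinct
calls flags all of them; such pileups are typically systematic error or
decoy-region artifacts. A sliding window was chosen over fixed tiles
because tiling makes the flag depend on an arbitrary phase.

Calls are written as VCF 4.2: symbolic ALTs for intrachromosomal types
with the orientation in the Delly-style `CT` key, breakend pairs with
bracket ALTs and `MATEID` for interchromosomal junctions, `CIPOS`/`CIEND`,
gap size, support counts in `GT:GQ:DV:DR`, and `LINKID` joining
complementary 3'–3'/5'–5' inversion junction pairs. Reading a written
file restores the identical call model.

## Repeat tracks and post-filters

Nanopore base calling collapses homopolymer stretches, which shows up as
spurious indel calls; tandem repeats behave similarly. The homopolymer
track marks maximal single-base runs of at least `min_run` bp (default 5),
expands each by a 1 bp border and merges the results, so common
`XXXXXYZZZZZ` motifs become one region. Tandem repeats are consumed as a
BED file (e.g. the UCSC simple-repeat table); no de-novo STR detection is
attempted. A call is discarded only when *both* breakpoint coordinates
fall inside the merged repeat union — the breakpoint itself is tested,
not its confidence interval, which keeps the filter conservative when CIs
are wide. A separate size filter removes deletions and insertions below
40 bp, which do not typically produce a split alignment and are dominated
by indel sequencing error. The two filters commute.

## The random-forest call filter

Twelve alignment-evidence features summarize each call, all constructed to
be read-depth and read-length independent: per-side means of mapping
quality, PID and aligned read fraction; the four distances from the median
breakpoints to their CI bounds; total breakpoint depth normalized by the
sample mean coverage; and the variant allele fraction. Side 1/side 2
always refer to the lower/higher genomic coordinate. The sample mean
coverage is the global mean (aligned bases over genome length); a
chromosome-local estimator would differ only under strong aneuploidy,
which the filter is not meant to model.

Training takes TP/FP labels (in practice: overlap with curated call sets,
via the set-intersection rule below) and runs 100 bootstrap rounds of
90/10 train/test splits, accumulating precision–recall curves over a fixed
score-threshold grid; the reported curve is the mean with a 95% interval.
The operating threshold maximizes recall subject to mean precision at or
above the target (default 0.82), breaking recall ties toward higher
precision, and the final forest is refit on all data. Forest
hyperparameters are fixed at 500 trees with the square-root-of-p default
for per-split features — the standard randomForest defaults; nothing in
our experiments motivated tuning them. Training is seeded and
bit-reproducible. Because the package ships no curated human truth data,
a synthetic labelled-feature generator is provided whose class separations
follow the qualitative importance ordering observed on real long-read call
sets (allele fraction dominant, then PID and aligned fraction, mapping
quality least); it exists to exercise the training machinery, not to
transfer to real data.

## Read-backed phasing

Given heterozygous SNVs with known parental alleles, the probability that
a read base call supports an allele is `1 - 10^(-q/10)` on a match and
`10^(-q/10)` otherwise. Per-read haplotype likelihoods multiply these
probabilities over all overlapped phase-informative SNVs; we work in log
space throughout because the raw products underflow for reads spanning
hundreds of SNVs. Deleted bases contribute nothing (the site is absent
from the pileup), and quality-0 calls are skipped — the support formula
degenerates to 0/1 there, which would let a single worthless base call
dominate the product. Ties give an `unknown` phase; there is no random
breaking. A minimum-informative-SNV threshold is exposed (default 0)
because reads with very few informative sites are the dominant source of
wrong assignments.

An SV is phased by pooling its junction-supporting reads and its
reference-supporting reads separately: per-set log-likelihood sums,
normalized to probabilities, each set assigned its argmax haplotype. The
SV counts as phased when the two sets land on *different* parental
haplotypes — the expected configuration for a heterozygous variant. The
phasing quality is the literal transform
`PP = -10 log10(max(Pp_SV, Pm_SV) × max(Pp_REF, Pm_REF))` of the
normalized maxima; note its direction: 0 at maximal confidence, rising
toward `-10 log10(0.25) ≈ 6` at total ambiguity. An error-probability
transform (of `1 -` the maxima) would rise with confidence instead; we
implement the printed definition and document the direction here rather
than silently invert it.

## Rearrangement reconstruction

To recover structure beyond single junctions, aligned segments of one
haplotype (in practice: the paternal set plus unphased reads) are merged
into graph nodes, with edges between nodes co-supported by two segments of
one read, weighted by supporting reads. The merge rule in the source
description requires two *other* segments of the node to extend at least
20 bp past the candidate's start; read literally this can never bootstrap
a node beyond a singleton, so we additionally let the first pair of
overlapping segments seed a node (one supporter suffices when the node has
a single member) and require the candidate to overlap the node interval,
preventing merges between distant segments. Contigs are maximal paths
using edges of weight at least 2, grown greedily from the
highest-total-weight unused node by locally heaviest edges, ties broken by
node span and coordinate for determinism; each node and edge is used once.
Edge records carry the majority relative orientation of their supporting
read pairs so inverted segments chain with the correct sign.

Independently of read evidence, derivative chromosomes are reconstructed
from a junction set alone: the reference is partitioned at the junction
breakends, each breakend consumes the matching segment end (3' for `+`,
5' for `-`), and chains are walked from free (telomeric) ends, flipping
orientation as ports dictate. Reference segments attached to no junction
are deletion-bounded and appear in no chain. A port demanded twice marks
an inconsistent junction set; the conflict is reported and partial chains
emitted. With centromere annotations each chain is checked to contain
exactly one.

## The simulator and what it shows

The simulator shatters a region of a (synthetic or supplied) chromosome:
cut positions are drawn with a minimum spacing (default 1 kb) enforced
also against the region edges, segments are permuted uniformly and flipped
independently with probability 0.5, and truth junctions are read off the
adjacencies, canonicalized with exactly the caller's convention, and
deduplicated; adjacencies that restore reference collinearity yield no
junction. The shatter region is placed *inside* the chromosome with
flanks longer than essentially any read (100 kb in the benchmark setup)
— breakpoints near a sequence end would otherwise lose coverage purely
through the read-sampling edge effect, a geometry artifact rather than a
property of the method. Heterozygosity is simulated by mixing
derived-haplotype and reference-haplotype reads at equal coverage.

Reads have log-normal lengths (mean 16.2 kb, σ_log 0.6 — the length scale
of recent nanopore genome runs; σ_log is our choice, as only the mean is
anchored), uniform positions and random strands. Sequencing error is a
stationary i.i.d. model with mismatch 5.1%, deletion 9.1% and insertion
0.9% — the error profile of R9.4-era nanopore data, deletion-dominated.
The generator is layered: the *layout* layer (always computed) draws
binomial error counts per true source segment, from which read offsets,
read lengths, PID and a quality value consistent with the realized error
rate follow; the *sequence* layer materializes error-injected base
strings on demand for FASTQ output, placing exactly the layout's error
counts. The split-read caller consumes only layout-level quantities, so
the two layers describe the same simulated data; unit tests verify the
sequence layer against the layout (exact substrings at zero error,
Hamming distance at the mismatch rate, length contraction at the indel
rates). What the i.i.d. model deliberately omits from real nanopore data:
homopolymer-conditional error inflation (an optional deletion-rate
multiplier inside homopolymers, e.g. 2.6×, is available when sequence
context exists), GC-dependent coverage bias, and basecaller-specific
error correlations.

Oracle alignment converts the provenance of each read into split
alignments with no mapping noise, while emulating two real limits of
split-read alignment: collinear neighbours with a reference discontinuity
under 50 bp are aligned through (the discontinuity absorbed as a
deletion in one record) — this is why ~40–50 bp events are structurally
invisible to split-read calling — and terminal anchors under 50 bp are
clipped. Evaluation matches calls to truth greedily one-to-one, requiring
equal chromosomes and orientations and both coordinates within 100 bp.
The benchmark scale used by the tests and the acceptance script is a 5 Mb
region carrying 125 breakpoints — the same breakpoint density as the
full-scale experiment (501 per 20 Mb) at a quarter of the sequence; with
an external aligner and a real chromosome the full-scale run is
reproducible but is not desk-scale.

Passing these benchmarks shows that the clustering, typing, genotyping and
evaluation machinery is correct under idealized alignment; it does not
show robustness to mapping ambiguity in repeats, reference bias, or
basecaller error structure, which enter only through real alignments.

Finally, two SV call sets are intersected with the standard rule: start
and end confidence intervals closer than 101 bp, plus — for
sub-kilobase events, insertions excepted — at least 70% reciprocal
overlap, so that distinct small events in close proximity are not
conflated. Matching is greedy one-to-one by CI distance.

## Parameter summary

| Parameter | Default | Meaning |
|---|---|---|
| `q1` | 20 | mapq below which a segment becomes an alignment gap |
| `d` | 10 bp | per-side clustering distance |
| `min_support` | 2 reads | minimum distinct supporting reads (`>=`) |
| `flank` | 100 bp | flank required of reference-crossing segments |
| `p_genotype` | 0.001/0.5/0.9 | allele-support probabilities per genotype |
| `q2` | 80 | MapQual threshold (median support mapq `<=` flags) |
| `cluster_window`, `cluster_min` | 1000 bp, 3 | SV-density flag |
| `min_run`, `border` | 5 bp, 1 bp | homopolymer run and border |
| `min_size` | 40 bp | small-indel drop |
| `precision_target` | 0.82 | RF operating-point precision floor |
| `match_window` | 100 bp | truth-matching window |
| `proximity`, `recip`, `size_cut` | 101 bp, 0.70, 1000 bp | set intersection |
| `min_split`, `min_anchor` | 50 bp, 50 bp | oracle split/anchor limits |

## Known limitations

The caller emits one SV per junction cluster; multi-junction events are
linked (inversions, breakend mates) but not jointly re-typed. Insertions
are sized by the unaligned gap only; no consensus of the inserted sequence
is built. The oracle aligner cannot stand in for a real aligner's
behavior in repeats. The reconstruction chains assume each segment end
participates in at most one junction, which excludes duplicated breakpoint
reuse. Phasing assumes the supplied SNV phase is correct; switch errors
in it propagate directly.
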