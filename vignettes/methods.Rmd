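---
title: "Methods: repeat-annotation concordance and downstream TE analysis"
author: "teconcord"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repeat-annotation concordance and downstream TE analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teconcord)
```

## The problem

De novo repeat finders are built for different targets — interspersed
transposable elements, tandem repeats, low-complexity sequence — and their
masks of the same assembly can differ by an order of magnitude in span.
`teconcord` treats those masks as first-class data: it quantifies how much
tools agree, at which genomic locations, and what any chosen annotation
implies downstream (TE composition and chromosomal distribution, repeat
contributions to gene structure and gene age classes, classifier
reliability, and direct evidence of recent transposition from synteny).
Everything operates on intervals; sequence is never required, which keeps
the full pipeline deterministic and desk-scale.

## Coordinate and interval model

Internally all intervals are 0-based, half-open (the BED convention):
`end - start` is the length, and abutting intervals share one coordinate.
GFF3 input (1-based, inclusive) is converted at the boundary. Three
deliberate conventions:

* **Touching intervals merge.** A base-level mask has no meaningful
  zero-width gap, so `merge_intervals()` is closed under adjacency.
* **Strand is ignored.** Every overlap analysis here is strand-agnostic;
  repeat masks rarely carry reliable strand anyway.
* **Out-of-range records are rejected, not clipped.** An element extending
  past its chromosome end signals a mask/index mismatch and should fail
  loudly.

The algebra (merge, intersection length, coverage fraction, per-window
coverage) is computed with IRanges/GenomicRanges reductions and coverage
run-length encodings; per-window covered bases come from `viewSums` over a
0/1 coverage vector and are therefore integer-exact, which is what makes
the conservation identity — window covered bases summing exactly to the
class's merged masked bp — testable as an equality rather than a tolerance.
The test suite checks all four primitives against an independent per-base
boolean-array oracle on a thousand random miniature genomes.

## Window concordance

Windows are consecutive, non-overlapping, tiled from coordinate 0; the
trailing partial window is kept so window lengths always partition the
genome (callers may drop short tails). The presence rule is *any overlap*:
one masked base marks a window as repeat-containing for that tool. The rule
is the simplest reading of "window contains repeats"; a `min_bases`
argument is exposed for stricter variants.

Method clustering is agglomerative complete linkage on Euclidean distances
between the binary window columns, computed from the full method × method
distance matrix (methods are few, windows many). Methods are sorted
lexicographically before clustering, so the dendrogram is deterministic and
invariant under input order — a property the tests assert directly.

Pattern abundance ranks the distinct 0/1 row patterns by window count,
ties broken lexicographically. The all-zero pattern is excluded: windows no
tool masks carry no information about tool relationships, and including
them would swamp the ranking on any genome that is mostly non-repetitive.

Pairwise agreement is **base-level** by default, normalized by the compared
method's mask: `agreement(a → ref) = |a ∩ ref| / |a|`. This is asymmetric
by design — the natural question is "how much of tool *a*'s mask does the
reference corroborate?", and it makes agreement 1.0 for any tool whose mask
is a subset of the reference. A window-level mode (fraction of *a*'s
presence windows also marked by the reference) is available via `mode =
"window"`; base-level is the default because it does not depend on a window
size.

## TE profiles

Composition is reported in two views because they answer different
questions: merged bp per class (how much sequence) and raw element counts
(how many annotated regions — fragmented annotations inflate this, which is
exactly why both are shown). Classes are merged independently; nested
same-class elements count once. Because some classifiers cannot separate
Penelope elements from LINEs, a `merge_penelope` flag folds the former into
the latter in both composition and density functions.

Density profiles use 5-kb windows by default — coarse enough to smooth
single elements, fine enough to show arm/center structure on megabase
chromosomes. Densities are computed on the *merged* per-class mask (the
defensible choice when element fragmentation varies by tool; the
alternative would double-count overlapping raw elements).

## Repeat–gene overlap

Two rules, matching two different questions:

* **Full containment** (single-exon transcripts only): the exon lies
  entirely within the merged per-class mask. Containment is tested against
  the merged mask by default so that a repeat annotated as several abutting
  fragments still contains an exon; `raw_elements = TRUE` requires one raw
  element to span the exon, reproducing the behaviour of an element-wise
  BED intersection with full-overlap required. Multi-exon input is an
  error, not silently filtered: the caller should make the single-exon
  selection explicit.
* **Fractional coverage** (isoform-merged genes): an (exon, class) record
  is emitted when the merged class mask covers at least `min_frac` of the
  exon. The boundary is inclusive — "at least 50%" includes exactly 50% —
  and the fixture generator plants exons at exactly 0.5 to pin the
  boundary, plus 1-bp-short variants to pin the exclusion.

Superfamily attribution goes to the raw element with the largest overlap;
ties go to the lexicographically first label, with all tied labels kept in
a secondary column, so results are deterministic and no information is
dropped. The superfamily tally counts distinct transcripts (a transcript
covered twice by the same superfamily counts once) and retains
superfamilies with at least 20 transcripts by default — the conventional
cutoff for calling a superfamily a strong candidate for activity.

## Phylostrata

The age class of a gene is the largest index, along a nearest-to-farthest
species ladder, of a species with a qualifying homology hit (strictly below
the e-value threshold, default 1e-5), and 0 when there is none. Gaps in the
hit row are allowed and irrelevant — only the most distant hit matters —
and the tests include non-monotone rows to pin that rule. Homology search
itself is out of scope: hit tables are inputs, which keeps the module
deterministic. Per-age-class contribution tables report, for every repeat
class, the count and fraction of genes with at least one qualifying
overlap; empty age classes yield `NA` fractions rather than a misleading 0.

## Classifier consensus

Voting happens at the class level (DNA transposon vs retrotransposon vs
other/unknown) because that is the granularity at which heterogeneous
classifiers can be meaningfully compared; order-level voting exists behind
a flag. With three voters a majority needs two agreeing labels; `AMBIGUOUS`
arises only through the other/unknown channel. Error rates are measured
against external truth when supplied (e.g. protein-domain evidence) and
otherwise against the majority consensus with ambiguous elements excluded
from the denominator — the exclusion is a documented choice: counting
undecidable elements as errors for every method would penalize all methods
equally and informatively for none.

## Synteny screening

Anchor candidates are ortholog families present exactly once in each
scaffold — multi-copy families (transposons above all) can never anchor but
can be insertion targets. Because anchors are single-copy on both sides,
the longest common subsequence of anchor tokens reduces to a longest
increasing subsequence of matched positions, implemented in O(n log n) and
verified in the tests against a quadratic LCS dynamic program. Both
orientations are tried and the longer chain kept.

An insertion call requires: a run of target-family genes between two
anchors that are adjacent in *both* focal–outgroup alignments; at most
`max_gap` (default 2) intervening non-target genes, absorbing small local
rearrangements; and no target-family gene between the corresponding anchors
in either outgroup, i.e. synteny conserved between the outgroups and broken
only in the focal lineage. The rule is an explicit operationalization of
screening conserved syntenic blocks for a focal-specific transposon
insertion; by construction no call can involve a region where an outgroup
also carries the target family, which the tests check on every fixture.

## The synthetic-data generator

The generator defines the study conditions and is itself first-class,
tested code. Defaults: a 1-Mb single-chromosome genome carrying a 24%
repeat landscape (the upper end reported for nematode-scale assemblies;
~12% is the C. elegans-like lower bound) split across LINE (7%),
simple repeats (5%), DNA transposons (5%), LTR (3%), Helitrons (2%) and
Penelope (2%), with class-specific mean element lengths (150 bp simple
repeats up to 1.2 kb LTRs). Elements of all classes are placed jointly
without overlap by distributing the free space as uniform spacings, so
planted densities are realized exactly (the registry's bookkeeping is an
equality, not an estimate). Gradient modes ("linear", "arms") tilt the
placement density for testing chromosomal-distribution code; they trade
exact density for shape.

Six tools emulate a realistic suite: two correlated pairs — a
machine-learning/consensus pair (sensitivity 0.90, 3% false-positive span,
20-bp boundary jitter) and a low-complexity pair (0.80, 2%, 10 bp) — each
generated from a shared latent subsample of the truth with independent 5%
per-element membership flips, plus two independent tools (0.55/5% and a
deliberately narrow 0.25/1%). The flip construction makes partner tools
share ~95% of their elements, the structure window clustering should
recover; the acceptance suite requires recovery of both pairs as mutual
first merge partners in at least 95 of 100 seeds.

Other fixtures: gene models planted with exact containment (per-superfamily
counts 30/24/21 above and 8/5 below the tally cutoff), exact 50% coverage,
repeat-free genes, and two-isoform genes; hit tables drawing age classes
from stated proportions (30% focal-specific, echoing the roughly one-third
orphan-gene fraction in the motivating system, and a heavier oldest class)
with planted per-class overlap fractions rising from 6% to ~17–19% for
simple repeats and a dip at class 5; classifier labels with per-method
class-level flip rates (0.05, 0.15, 0.25); and three 500-gene orders with
5% local adjacent-swap shuffling and 20 planted single-gene focal
insertions of a multi-copy family token.

Reproducibility: one global seed feeds fixed per-generator substream
offsets, so adding a generator never perturbs existing fixtures; the RNG
kind is pinned, and identical configurations produce byte-identical files.

**What the generator does not emulate:** nucleotide sequence (and hence
sequence-divergence-driven detection failure), nested insertions,
annotation fragmentation correlated with element age, assembly gaps, or
biased chromosome-scale covariation between repeat classes. Passing tests
demonstrate that the algebra, rules and thresholds behave exactly as
specified on landscapes with known truth — not that any particular real
assembly's numbers will be reproduced.

## Problem sizes and runtime choices

The default study-scale conditions — 1-Mb genomes with six tools, 5,000-gene
hit tables over a 9-species ladder, 2,000-element label tables, 3 × 500-gene
orders — run each analysis in well under a second, so the property suites
(1,000 random genomes against the per-base oracle, 100 clustering and
classifier seeds, 50 synteny seeds) complete in minutes. Pipeline tests use
a reduced 200-kb configuration purely because determinism checks need two
full runs.

## Known limitations

* Agreement and concordance depend on the chosen window size; 1 kb is a
  convention, not an optimum, and very fragmented masks inflate any-overlap
  presence.
* The asymmetric agreement statistic is not a similarity metric; use the
  window-level mode when a symmetric comparison is wanted.
* Insertion detection assumes scaffold-scale collinearity; it picks, per
  focal scaffold, the outgroup scaffold sharing most anchors and will miss
  insertions at scaffold boundaries or in regions with fewer than two
  usable anchors (such scaffolds are skipped with a warning).
* Age classes inherit whatever biases the upstream homology search has;
  no correction for homology detection failure is attempted.
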