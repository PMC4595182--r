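---
title: "Satellite DNA detection, alignment and family clustering with satkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Satellite DNA detection, alignment and family clustering with satkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satkit)
```

## The problem

Satellite DNA consists of long tandem arrays of a repeated unit. In
nematode genomes these arrays are abundant, unevenly distributed along
chromosomes, and of particular interest on holocentric chromosomes, where
kinetochore-competent (CENP-A binding) chromatin is dispersed rather than
confined to one centromere. Studying them requires four capabilities that
this package provides as one tested toolchain: finding the arrays,
comparing their repeat units, grouping them into families within and across
species, and scoring them against a chromatin affinity track.

## Detection model

A satellite is operationally defined as an array of at least 10 repeats of
a 10–200 nt unit. Detection proceeds in four steps.

**Seed clustering.** Every decamer that (a) contains no N, (b) has no
internal repetition (its minimal string period equals 10 — `ACACACACAC`
is a dinucleotide pattern, not a decamer seed), and (c) occurs at least 10
times within some 2,000-base region marks a candidate locus. The
within-window test slides a two-pointer over each decamer's sorted
occurrence list instead of tiling the contig into fixed 2 kb blocks;
tiling would miss clusters straddling block boundaries. The chance of a
false seed cluster is negligible: the expected number of times a pattern
of length $L$ recurs $n$ times in a random sequence of length $N$ is
$RE = N\,(4^{-L})^n$ (`random_expectation()`, evaluated in log space), far
below 1 for $L = 10$, $n \ge 10$, $N = 2000$.

**Extension.** From a candidate, the array is extended while further
occurrences of the seeding decamer lie within `max_gap` bases (default: the
window size, 2,000; no tighter figure is defensible a priori for
"neighbouring"). This is single-linkage chaining of the seed's occurrence
list, so arrays longer than one window are recovered in full, and two
arrays of the same unit separated by more than `max_gap` stay separate.

**Segmentation.** The repeat length is the modal distance between
consecutive seed occurrences; unit boundaries are anchored at the first
occurrence and cut at successive occurrences. Two refinements make
segmentation robust to point mutation, which removes individual seed
copies. First, a gap that is close to $k$ modal lengths (within $\pm k$
bases, one indel per period) is subdivided at modal-length multiples, so
each period contributes one unit; without this, an array whose copies are
individually mutated is under-counted and wrongly rejected by the
10-repeat minimum. Second, a gap longer than about six periods cannot be a
run of lost seeds and is treated as a non-repeat spacer: the chain splits
there and each block is evaluated separately. This guards against a chance
occurrence of the seed decamer near (but outside) the array dragging
unrelated sequence into the reported interval. Units always concatenate
exactly to the reported genomic interval.

**Regularity filter.** Arrays keep only if at least 30 % of their units
have exactly the modal unit length; the comparison is inclusive, so a
10-unit array with 3 modal-length units passes. The filter's own
significance is given by the expected number of equal-length fragments in
a random partition, $RE = \binom{n}{k} L^{-(k-1)}$
(`equal_length_expectation()`); for 3 of 10 fragments in a 2 kb array this
is $3\times10^{-5}$, so regular arrays essentially never arise by chance.

Overlapping satellites with the same modal repeat length are merged by
re-segmenting the union with the dominant seed; with different repeat
lengths the longer one is kept (one locus, one satellite).

## Alignment of repeat units

Tandem-repeat units are defined only up to cyclic rotation and strand, so
`pairwise_score(a, b)` maximises a global Gotoh (affine-gap) alignment
score over both orientations of `b` and all of its rotations. The search
enumerates rotations explicitly in compiled code; at unit lengths up to
200 nt the cubic cost is a few milliseconds, and enumeration is exact —
tests verify it against an independent dynamic-programming oracle over
explicitly enumerated rotations. The default scheme is +1 match, −1
mismatch, −2 gap opening, −1 per gapped base (a standard nucleotide
scheme; the published description of the original aligner gives no
numbers, so the scheme is configurable). `N` never matches anything,
including another `N` — a conservative treatment of assembly uncertainty.

The raw score is normalised by its maximum attainable value,
$\text{match}\times\min(|a|,|b|)$ — a perfect alignment of the shorter
sequence — giving a score in $[0,1]$; negative raw scores (typical for
unrelated sequences under this scheme) floor at 0. The floor creates an
atom at 0 in the null distribution, which is why calibration statements
about mid-range quantiles are made on the continuous upper region of the
null. Ties between equally scoring placements resolve deterministically:
forward strand before reverse, smallest rotation first.

Per-satellite consensus units are built by rotating every unit into the
first unit's frame (as the best alignment dictates) and taking per-column
majorities over the units of modal length; ties break in the fixed order
A < C < G < T.

## Score calibration

Significance of observed scores is measured against an empirical null:
i.i.d. random sequence pairs at the satellite-like base composition (30 %
A, 30 % T, 20 % G, 20 % C), scored identically, stratified by sequence
length (10 nt buckets). P-values use the add-one estimator
$p = (1 + \#\{\text{null} \ge s\})/(1 + n)$, never exactly zero; resolving
$p < 10^{-4}$ therefore needs at least $10^4$ null pairs. A second,
operational decision rule is the length-adjusted regression threshold
$(-0.2837\,\ell + 66.0155)/100$ on the normalised score, floored at 0
(the line crosses zero near $\ell = 233$ columns; behaviour beyond that is
otherwise unspecified). Cross-species family links must pass both
instruments.

## Families and super-families

Within a species, satellites are clustered on their consensus units (not
on every raw repeat — the consensus is what defines the family, and it
keeps the score matrix tractable). Progressive agglomeration merges the
highest-scoring pair of clusters, recomputes the merged cluster's
consensus from its members' consensuses, refreshes its scores against the
other clusters, and stops when the best score falls below the threshold
(default 0.6). Unmerged satellites are single-member families. The merge
gate is the pairwise consensus-vs-consensus score; a profile score is the
other defensible choice, but the published description does not specify
one, and consensus gating keeps the rule identical within and across
species. Deterministic tie-breaking (scores, then positions) makes the
partition invariant to input order, and raising the threshold only refines
the partition.

Families are named `Spp_Fam_a_b_c`: `a` ranks by member count (ties by the
earliest first-member position), `b` is the consensus length, `c` the
member count. "Large families" have 10 or more members.

Across species, every family-consensus pair from different species is
aligned; pairs passing both the empirical-null gate (p < 1e-4) and the
regression threshold become edges, and connected components (single
linkage) are super-families. The species-set table behind a Venn summary
and per-species species-specific fractions are reported alongside.

## CENP-A affinity

Affinity tracks arrive as WIG files with log-scale values; the base of the
logarithm is not recorded in such files, so it is a parameter
(`log_base`, default 2, the usual scale of ChIP ratio arrays; e and 10
are accepted). Each satellite's score is the mean of the antilogged values
over the track positions its interval covers — uncovered positions are
excluded, not imputed, and a satellite with no coverage is excluded from
downstream classification. Satellites split into two (near-)equal groups
at the median score; "high" means strictly greater than the median, so
with an odd count the median element is "low". Enrichment of a subset
(default: longer than 2 kb with repeats longer than 160 nt) in the high
class is a one-sided Fisher exact test on the 2×2 table, with the
two-sided value also reported since the direction convention is a choice.

## Microsatellites

Microsatellites are maximal perfect tandem runs of 1–3 nt motifs (4–6 nt
optional) of at least 24 nt total — no impurity allowance, which keeps
calls exactly reproducible. Motifs are canonicalised to the
lexicographically smallest rotation of the motif or its reverse
complement, pooling AG with GA, CT and TC. Maximal runs of different
periods can share a few boundary bases (the last G of a G-run also starts
a GAGAGA frame); overlaps resolve to the longest run, with shorter runs
trimmed to their free bases and kept if still 24 nt. A run is assigned the
smallest period that explains it (an A-run is a mononucleotide call, never
a degenerate AA dinucleotide call). `W` tracts — maximal runs of A/T at
least 24 nt that are not already A, T or AT microsatellite calls — are
counted separately, as the residual "random" A/T sequence class.

## The simulator, and what passing tests mean

`simulate_genome()` builds i.i.d. background at the 30/30/20/20
composition and splices in planted arrays copy by copy, applying per-base
substitutions and optional single-base indels per copy, so the truth set
records exact intervals, units and copy numbers. Random insertion points
keep 5 kb of background between plants so that neighbouring arrays are not
chained into one satellite by the 2 kb extension rule.
`simulate_track()` draws log-scale values from two shifted normals (means
−0.5 outside and +1.5 inside designated high-affinity regions, sd 0.5, on
the log2 scale, sampled every 10 bases) — enough structure to exercise
scoring, classification and enrichment with known answers.

The standard validation fixture is a 100 kb genome with five planted
arrays (units 12–40 nt, 15–30 copies). Exact plants must be recovered with
both boundaries within one repeat unit; under 5 % per-base per-copy
mutation, recovery is assessed by reciprocal overlap instead, because
terminal copies that lost their seed decamer cannot anchor a boundary —
the array is found, with the correct repeat length, but may end a few
degraded copies short. Family-recovery fixtures draw members at exactly
bounded divergence (at most 10 % of positions substituted), matching the
stated condition; a binomial rate of 0.1 occasionally realises far higher
divergence on short units, which correctly fails the 0.6 rule and would
test a different condition.

These simulations emulate array structure, composition and degradation,
not everything about real assemblies: no higher-order repeat structure,
no transposon insertions inside arrays, no assembly collapse of long
arrays, no correlated mutation. Passing them shows the algorithms
implement their definitions correctly and are robust to point mutation at
the stated level — not that real-genome catalogs are complete, since those
also depend on assembly quality. Full-scale catalog reproduction
additionally requires the external genome releases and affinity track, and
exact counts depend on unpublished details of the original detection and
alignment programs; the package's defaults encode the published protocol
parameters (decamer seeds, 2 kb windows, 10 repeats of 10–200 nt, 30 %
regularity, 0.6 family threshold, p < 1e-4 cross-species gate, 24 nt
microsatellite minimum).

## Problem sizes and numerical choices

The shipped tests and the acceptance script run on 100 kb fixture genomes
(5 plants, 20 replicate seeds for the mutation and family studies), nulls
of 2,000–10,000 pairs at unit lengths 30–40, and alignment oracles over
200 short pairs — sizes chosen so the full validation suite completes in a
few minutes on one core while every statistical check retains enough
resolution (a 10,000-pair null resolves p < 1e-4; 2/√n calibration slack
at n = 2,000 is ±4.5 %). Scores are compared exactly where the algorithm
is exact (invariances, oracle equivalence) and with 1e-9 tolerance where
floating-point order of operations may differ (symmetry). Degenerate
inputs are defined, not left to chance: empty sequences error, empty
catalogs give empty (not absent) results, all-tied affinity scores flag
the median split as degenerate, and empty 2×2 margins report an undefined
p rather than a number.

## Known limitations

* Seeds are exact decamers: arrays whose every copy of every decamer is
  mutated (per-copy divergence well above ~10 %) are invisible, by design.
* Repeat lengths above 200 nt cannot reach 10 seed copies in a 2 kb window
  and are out of scope, matching the published detection ceiling.
* The progressive clustering recomputes consensus-vs-consensus scores, not
  profile alignments; deeply diverged family members beyond the 0.6 radius
  of the consensus become singletons.
* WIG parsing covers fixedStep and variableStep blocks; bigWig and
  compressed archives are out of scope.
* The CENP-A module scores intervals against a given track; it does not
  call affinity domains or peaks.
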