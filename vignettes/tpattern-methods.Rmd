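---
title: "Detecting hierarchical temporal patterns in categorical event series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting hierarchical temporal patterns in categorical event series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The data and the pattern model

The package operates on *T-data*: one or more samples of discrete
occurrence-point series, each series recording the times (positive
integers, in whatever unit the data were coded in) at which one
categorical event-type occurred, all within an observation period
`[1, T]`. Multi-sample recordings are concatenated onto one axis with
recorded sample boundaries; all baseline probabilities use the
concatenated period and total counts, and no statistic ever relates
points across a boundary.

A *T-pattern* is an ordered set of components `X1 ... Xm` — event-types
or, recursively, other T-patterns — that recurs such that the distance
from each component to the next falls within a component-pair-specific
*critical interval* `[d1, d2]` (0 ≤ d1 ≤ d2) significantly more often
than expected if the components were scattered independently. A pattern
of length `m` is represented as a binary tree with `m` terminals and one
critical interval per internal node, relating the left part's end to the
right part's start, plus the list of dated occurrences `(start, end)`.
Detection is bottom-up: significant pairs of series become new working
series, pairs of pairs follow, and a completeness competition removes
redundant detections after each pass.

## The critical-interval statistic

For an ordered pair of working series (A left, B right) on a period of
`T` units, with `nB` points in the right series, the null model treats B
as independently present in each time unit with rate `q = nB / T`.

The relation sought is sequential — *an occurrence of B follows an
occurrence of A within `[d1, d2]`* — so both the candidate intervals and
the test statistic are built from the distance of each A point to its
**next following** B point in the same sample:

* Candidate intervals `[d1, d2]` take both endpoints from the set of
  observed next-following distances (capped at `dMax`).
* A left point is a *hit* when its next-following distance lies in the
  candidate interval; hits are counted as **distinct right points**,
  because n recurrences of "B follows A" require n distinct B
  occurrences (several A sharing one next B count once).
* Under the null, the next B point skips the `d1` units before the
  window and lands inside the (possibly boundary-truncated) window of
  width `w`, so the per-trial hit probability is
  `(1 - q)^d1 * (1 - (1 - q)^w)`. The p-value is the exact upper tail of
  the number of hits over the `|A|` trials — a binomial tail when all
  windows have equal width, otherwise the exact heterogeneous
  (Poisson-binomial) tail computed by a capped dynamic program.

Because the candidates are data-driven, testing every one of them at
`alpha` would make some spurious interval near-certain as soon as a few
dozen distances are observed. The scan therefore applies a
Bonferroni-style selection control: a candidate must reach
`p ≤ alpha / K`, where `K` is the number of distinct observed candidate
distances. `K`, not the quadratic number of `(d1, d2)` pairs, is used as
the family size because nested candidates sharing a seed distance are
near-duplicates of one another. The returned interval is the qualifying
candidate with the smallest p, ties broken by smaller width and then
smaller `d1`, which makes the search deterministic. The scan only
evaluates, for each `d1`, the narrowest `d2` attaining each distinct hit
count: a wider interval with the same hits has a larger or equal
p-value and loses the tie-break, so the pruning is exact.

Even with the selection control, detection at `alpha = 0.005` is not a
familywise error guarantee across all series pairs and levels — chance
collisions of next-following distances are statistically
indistinguishable from genuine two- or three-fold recurrences, and some
spurious intervals are expected in pure noise (we measure roughly 5% of
independent 20-point series pairs). That residual rate is deliberate:
making the per-pair test strict enough to silence noise entirely would
also erase the marginal two-occurrence signals the method is explicitly
meant to catch. The global assessment of how much of a detection run
chance can explain is the job of the surrogate validation below, which
is how this method family has always framed the question.

`ciPValue()` exposes the simpler fixed-interval tail (any B in the
window, plain binomial) for a user-chosen `[d1, d2]`; the two agree in
direction (the fixed-interval hit count is always ≥ the next-following
count, so its p-value is ≤ the scan's at the same interval).

## Pattern construction

Each pass tests every ordered pair of distinct working series whose
lengths sum to at most `maxLength`, relating left end-points to right
start-points. A significant interval yields a candidate pattern by
greedy earliest matching: left occurrences are scanned in time order and
each takes the earliest unused right occurrence whose start follows its
end by a gap in `[d1, d2]` within the same sample. Two safeguards:

* **Zero-gap point reuse.** With `d1 = 0` a pattern could otherwise pair
  with a series through the very point that is already its own first or
  last terminal, producing degenerate chains like `(a [0,0] (a ...))`
  with near-zero p-values. A zero-gap match that would reuse the same
  (series, time) point in both parts is skipped in favor of the next
  eligible right occurrence.
* **Self-pairing** of a working series with itself is allowed only in
  burst mode.

Candidates with at least `nMin` paired occurrences enter the
completeness competition together with all previously surviving
patterns. Competition applies two rules: (1) a pattern is dropped when
another pattern with equally many occurrences realizes each of its
occurrences *with the very same terminal points* as part of a longer
terminal sequence — point-level identity matters, since an unrelated
pattern that merely spans the same stretch of time is not a more
complete detection of the same thing; (2) among patterns with identical
terminal sequences and occurrence lists but different tree shapes, the
one with the smallest maximal node p-value survives. Survivors join the
working set; the search stops at a fixpoint or after `maxLevels`
passes. Identical input always yields identical output.

`verifyTPattern()` re-checks every reported pattern against the raw
data without trusting the builder: terminal conservation, per-node gap
containment, sample containment, point-reuse, occurrence counts and node
p-values. The test suite runs it on everything detection returns, and
an independent brute-force enumerator (naive quadratic scan, naive
pairing, naive competition) must reproduce the full surviving pattern
set on micro-instances.

## T-bursts

A T-burst is a univariate dense run: the series is related to itself
with fast intervals `[0, d2]`, `d2` drawn from the observed
successive-point gaps, a point counting as a hit when its next point
follows within `d2`. The null rate excludes the focal point
(`(n - 1) / T`). No minimum hit count beyond 1 is imposed — a single
sufficiently improbable doublet (two points a unit apart on a very long
period) is already a significant burst, and every burst instance
requires at least two points by construction. Instances are the maximal
runs with internal gaps ≤ `d2`; the burst joins the working set so it
can become a branch of larger patterns (where a stand-alone burst is
absorbed by a larger pattern using the same points and count, that is
the competition working as intended).

## Sequences and the [1,1] mode

`sequenceToTData()` maps a symbol string (text with separators removed,
DNA, protein) to T-data: position i of symbol s becomes point i of
series s. In mode `"fixed11"` only the interval `[1, 1]` is tested
(at `alpha` itself — the family has one member), which makes detection
assemble recurrent contiguous strings bottom-up: digrams, then
tetragrams, and so on, the competition discarding every substring that
occurs exactly where a longer recovered string occurs. A 21-letter word
planted twice in a background that shares none of its letters is
recovered whole as a single pattern; with a uniform 26-letter background
the same word is not recovered, because none of its letter pairs is
significant against the busy baseline — the known blind spot of strictly
binary-tree assembly, which higher-order trees would address.

## Surrogate validation

`monteCarloValidate()` compares the number of distinct detected patterns
of each length against surrogates built by either *shuffling* (each
series redrawn uniformly without replacement within its sample,
destroying all temporal structure) or *rotation* (each series shifted
circularly by its own random offset within its sample, preserving the
circular inter-point interval multiset). Surrogate runs use
byte-identical parameters. The report is descriptive — per-length
observed count, surrogate mean and population SD — mirroring the
mean-plus-one-SD comparison conventional for this method family. The
conservation laws (shuffle preserves per-sample counts; rotation
additionally preserves circular gap multisets) are asserted as tests.

One calibration subtlety is worth stating: on pure-noise data the
observed run is statistically exchangeable with its shuffle surrogates,
so whenever exactly one replicate among the 21 shows some rare
long-chain length, the observed run is that replicate with probability
1/21 ≈ 4.8%. A per-length mean-plus-3-SD envelope therefore sits at
roughly a 95% pass rate by symmetry alone; our suite measures 92% over
50 seeded replicates at the sizes below, and the corresponding
acceptance check is accordingly strict to the point of occasional
failure. This is a property of the comparison scheme, not of the
detector.

## Parameters

| Parameter   | Default | Meaning |
|-------------|---------|---------|
| `alpha`     | 0.005   | Per-test significance level. The level is a user decision in this method family; 0.005 is its conventional default. |
| `nMin`      | 3 (floor 2) | Minimum pattern occurrences. Multi-sample files accumulate occurrences across samples, so the right value depends on total, not per-sample, exposure. |
| `dMax`      | `T − 1` | Cap on interval ends, in time units. |
| `maxLevels` | 10      | Construction passes; patterns can double in length each pass (30 for sequence mode, where growth is near-linear). |
| `maxLength` | 10      | Terminal-count cap (30 for sequence mode). |
| `mode`      | general | `general`, `burst` (adds univariate burst detection), `fixed11` (sequence mode). |

## Synthetic data: what it emulates, what it does not

The generators supply the study conditions for every test: independent
uniform background series (`generateNoiseTData()`), planted hierarchical
instances with fixed or jittered gaps and non-overlapping spans
(`plantPattern()`, which returns machine-checkable ground truth), and
random text with planted words (`generateTextWithPlants()`). They
deliberately do **not** mimic serial dependence within series,
cross-series rate drift, bout structure of real behavioral codings, or
natural-language letter statistics; a planted-recovery result here shows
correctness of the machinery under its own null, not performance on any
particular real corpus.

Problem sizes used by the suite, chosen to keep the full run desk-scale:
detectability scans use a 10^4-unit period with three involved series
(10 noise points each on top of the planted instances) and five 10-point
background series; calibration uses six 12-point series per replicate
with 20 surrogates and 50 replicates; word recovery uses a
10,103-letter text. A 20-series × 20-point all-noise detection runs in
about ten seconds and is exercised once, not inside the replicated
loops.

## Known limitations

* Strictly binary trees: patterns whose parts are only significant as
  wholes (no significant pair) are invisible, as the word example
  above demonstrates on purpose.
* No substitutes/alternatives at pattern positions; each variant is a
  separate pattern and must recur on its own.
* The significance level is user-chosen; no automatic selection is
  attempted.
* Interval-valued events are handled only through the begin/end
  point convention of the label syntax (`actor,phase,behavior`).
* Detection p-values are selection-controlled per pair but not across
  pairs or levels; global error assessment is delegated to the
  surrogate comparison, per the method family's own practice.
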