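---
title: "Screening cis-regulatory elements against expression-phase backgrounds"
author: "crmscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening cis-regulatory elements against expression-phase backgrounds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crmscan)
```

## The problem

Short DNA motifs upstream of genes — cis-regulatory elements (CREs) — and
combinations of them (cis-regulatory modules, CRMs) shape when a gene is
expressed. Given (i) fixed-length promoter sequences ending at the
transcription start site (TSS), (ii) a catalog assigning each differentially
expressed gene to exactly one expression category (for circadian data, the
4-hour bin of its peak expression), and (iii) a list of candidate motifs,
`crmscan` asks: which motifs, and which motif pairs, occur preferentially in
genes of particular expression phases, and do candidate pairs show positional
structure (ordering relative to the TSS, preferred spacing, TSS-proximal
clustering)?

The screen makes no distributional assumption about expression values — only
the categorical assignment matters — and treats motif occurrence as a binary
per-promoter property. It is a correlational screen: a candidate call asserts
association between motif presence and expression phase, not causation.

## The candidate decision

For a query (a single IUPAC motif, or a comma-separated pair whose members
must both occur in a gene's promoter), the screen computes the distribution
of expression maxima (DEM): the percentage of the query's matched, cataloged
genes falling in each category. The DEM is compared with the all-genes
background distribution.

What counts as "far from background" is calibrated empirically: a background
replicate draws `n_random` random motifs (lengths 5–8 bp, i.i.d. uniform
bases by default), computes each one's DEM, and records the per-category
standard deviation. The query's absolute per-category deviation from the
background, divided by a replicate's per-category sd, is its deviation in sd
units; a replicate *flags* the query when any category reaches
`threshold_sd` (default 1). Because a single replicate's sd estimate is
itself noisy, `n_backgrounds` replicates (default 100) vote, and the query
is a **candidate** only if a strict majority flags it *and* it matches at
least `min_matches` promoters (default 20). Per-category votes define the
flagged categories; the direction of each deviation is reported separately,
the threshold itself being two-sided.

Design points worth making explicit:

* **Which motifs feed the sd.** The minimum-match rule is applied to
  *queries*; every random background motif with at least one cataloged match
  contributes its DEM. Rare random motifs have the noisiest DEMs, and it is
  precisely this noise that the sd must describe for the threshold to be
  conservative. Filtering the background to frequent motifs would shrink the
  sd and inflate the false-candidate rate several-fold (we verified this in
  a design-stage simulation of the hypergeometric DEM-noise model).
* **Zero sd.** In degenerate categories (sd exactly 0 in a replicate), the
  deviation is defined as 0 when the query's DEM equals the background there
  and infinite otherwise, so impossible deviations always flag.
* **Comparison baseline.** Query DEMs are compared with the catalog
  background, not with the random motifs' mean DEM; the two nearly coincide
  (the test suite asserts the resampling property
  `mean(random DEMs) ≈ background` within `2 sd / sqrt(n_random)`).
* **Orientations.** By default a motif may occur as written, reversed,
  complemented, or reverse-complemented ("all orientations"); palindromic
  collisions are deduplicated. Matching is exact after IUPAC expansion; an
  `N` in a promoter sequence never matches anything, since an unknown base
  is not evidence of an occurrence.
* **Coordinates.** Matches use 0-based offsets from the 5′ end; the TSS
  abuts the 3′ end, so a match's TSS distance is
  `region_length − (start + width)`. A k-mer index (word size 5 by default)
  accelerates matching; indexed and naive scans are property-tested for
  exact agreement.

Reproducibility across runs is summarized by the candidate-set overlap
(`|intersection| / |union|`) and the quartile dispersion coefficient
`(Q3 − Q1)/(Q3 + Q1)` of candidate counts. All quartiles in the package —
here and in Bowley's skewness — use linear interpolation between order
statistics (R's type 7), stated because the quartile convention changes
these coefficients at small n.

## Positional statistics of candidate pairs

Three per-pair features are computed over the promoters containing both
members:

* **Order test.** Count, per promoter, which member's TSS-nearest occurrence
  lies closer to the TSS (exact ties drop the promoter). Under the null each
  order is equally likely, so with `n` ordered promoters and `X` the count of
  the more frequent order, `p = min(1, 2 · Σ_{i=X..n} C(n,i) · 0.5^n)` — the
  doubled upper tail of the exact binomial. Doubling (rather than a
  minimum-likelihood two-sided rule) is stated because the conventions differ
  at even `n`; for the symmetric p = 0.5 case doubling equals exhaustive
  enumeration over all `2^n` outcomes, which the test suite checks exactly
  for every `n ≤ 20`.
* **Distance test.** Observed spacing is the minimum, over occurrence pairs,
  of the absolute difference of the members' TSS-proximal edge distances
  (edge-to-edge; a start-to-start option exists). The null is simulated:
  each member's expected occurrence count per promoter (total occurrences /
  total promoters, floored at 1 — a co-occurrence needs at least one of
  each) determines how many uniform positions are drawn on
  `[0, region_length)`; the smallest absolute pairwise difference is one null
  draw, and 10,000 draws form the null sample. A two-sided two-sample
  Kolmogorov–Smirnov test compares observed spacings (raw, unbinned) with
  this sample; with fewer than 3 observed values the p-value is not
  computed. The test's size is calibrated: sampling observations from the
  null itself rejects at ~5% (asserted within ±2% over 500 fixtures).
* **Bowley skewness of module position.** The module position is the
  smallest TSS distance of either member. Skewness of the position
  distribution is `S = (Q3 + Q1 − 2 Q2)/(Q3 − Q1) ∈ [−1, 1]`, computed on
  the promoter coordinate scale (TSS at `region_length`), so TSS-proximal
  clustering gives a left-skewed distribution and negative `S`. At least 4
  positions and `Q3 > Q1` are required.

## The network evolver

Candidate pairs are grouped by their three statistics with an ensemble of
two-class feedforward networks. Each network has one hidden layer of
`n_hidden` sigmoid neurons (`s(t) = 1/(1+e^{−t})`) and a single output
neuron with a Heaviside activation; `h(0) = 1` by convention (it must be
fixed for determinism). Inputs are fed raw — Bowley skewness in `[−1, 1]`
and the two p-values in `[0, 1]` — because the three negative-control points
`(order_p = 1, distance_p = 1, bowley ∈ {−1, 0, 1})` are defined on these
scales.

Training is evolutionary rather than gradient-based: a population of
networks is scored each *round*; the best `top_k` survive, and the next
round adds single-parameter incremental (± `step`) or disruptive (resample)
mutations, per-parameter crossovers of two elites, and fresh random
networks. Only weights and biases evolve — never the structure. A network's
score is lexicographic: any network classifying a negative-control point as
positive gets the sentinel minimum; otherwise the score is (number of
positives included) / max(1, number of random points included), with ties
broken toward networks including more points, so that equally enriched but
broader categories win. The random points — actual positional statistics of
random motif pairs on the same promoter set, with neutral values
`(1, 1, 0)` substituted where too few co-occurrences exist — are what stops
categories from growing without bound.

A *cycle* ends when the best score has stagnated for `patience` rounds; its
best network is kept and its positive members are marked categorized. In
subsequent cycles the score's numerator counts only not-yet-categorized
positives (a network adding none is rated lowest), and fresh networks are
constructed to include one uncovered positive by raising the output bias
until that point classifies as 1 — a direct mechanism for forcing new cycles
toward new categories. Training ends when every positive is categorized at
least once; a cycle cap aborts with a warning and a partial ensemble.

Three numerical choices matter for search quality on this piecewise-constant
score landscape (the score only changes when a training point crosses a
decision boundary): elites are deduplicated by their categorization
signature, so clones of one solution cannot crowd out stepping stones; the
stagnation clock only starts once the best admissible network is at least as
positive-dense as random-dense (ratio ≥ 1), below which the cycle keeps
exploring up to `max_rounds`; and unproductive cycles are retried with fresh
populations rather than aborting the run. Even so the optimizer is
stochastic: on the two-cluster benchmark fixture roughly 99% of runs recover
the two clusters as disjoint categories, and in the remaining runs a region
spanning both clusters that happens to include very few random points wins
the larger-category tie-break legitimately. Analyses that need the
finest-grained categories should therefore train a small number of
ensembles and inspect the category-distance matrix
(`1 − |A∩B| / min(|A|, |B|)`), which the reporting functions emit alongside
per-network Spearman correlations among the three inputs.

Defaults (all overridable via `cng_params()`): 3 hidden neurons, population
50, top 10 kept, 10 fresh per round, patience 15 rounds, initialization
uniform on `[−5, 5]`, incremental step 0.1, round cap 400, cycle cap 50.

## The synthetic fixtures

`standard_fixtures()` generates the study conditions used by the test suite
and the acceptance script. Promoters are i.i.d. uniform-base sequences of
1000 bp; catalogs use six 4-hour phase bins with weights
13/14/26/15/14/18%, mirroring a circadian phase distribution that peaks
before subjective dusk with a secondary peak before dawn. Plants *overwrite*
sequence windows (never insert), so positional arithmetic stays exact, and
every fixture returns a manifest of planted coordinates against which the
matcher and the positional statistics are verified.

* `null` — 100 promoters, no plants: the false-candidate calibration. At
  this scale the default `min_matches = 20` excludes random 7–8-mers, the
  same role the minimum-occurrence recommendation plays at genome scale,
  which is what keeps the false-candidate rate of fresh random queries below
  10% after the majority vote.
* `single_cre` — the evening element `AAAATATCT` planted in 30 of 100
  promoters at uniform positions, with planted genes assigned the `ZT8-ZT12`
  bin with probability 0.9: an enrichment several background-sds above
  threshold.
* `pair_order` — a G-box-like/`ACAGTACT` pair in 60 of 200 promoters. The
  module's TSS distance is drawn as `300·U³` bp (strongly TSS-proximal) and
  the first member is TSS-proximal with probability 0.95, but the member
  spacing is drawn from the spacing null itself, so the generative truth is:
  order preference yes, left skew yes, distance preference no. Spacings
  shorter than the proximal member's width are redrawn (members may not
  overlap), a truncation that removes under 2% of null mass.
* `pair_spacing` — the same pair at a fixed 50 bp spacing with unbiased
  order: the mirror-image pattern.
* `two_cluster` — a training-set fixture for the evolver: 16 + 8 positive
  points in two tight clusters and 80 random points whose cloud surrounds
  both clusters in every coordinate, so any category spanning both clusters
  sweeps up random points and scores below a tight single-cluster category.

What the fixtures do *not* emulate: real promoter base composition and
repeat structure, motif degeneracy in the planted signal, correlated motif
co-occurrence, expression measurement noise, and rhythmicity detection
(catalogs arrive as final gene-to-category assignments). Passing tests
therefore demonstrate that the statistics and the decision engine behave as
specified under their own model assumptions — not that any particular
biological dataset will yield the same candidate rates.

## Problem sizes used by the tests and the acceptance script

The suite runs the screen at the fixture scales above with the method's full
default settings (100 random motifs × 100 background replicates per model).
Calibration properties use 500 resampling fixtures (distance-test size),
10,000 random samples (skewness bounds), 20 seeded repeats (planted-signal
recovery), 5 seeds (candidate-set overlap) and 3 independent trainings
(two-cluster recovery); the acceptance script reports the same quantities at
10 repeats and 300 calibration fixtures. These sizes were chosen so each
stochastic assertion has comfortable sampling margins at the fixture scale.

## Known limitations

* Modules are pairs; the order test is binomial and does not generalize to
  three or more members without a multinomial replacement.
* The sd-threshold plus majority vote is the entire error control; no
  multiple-testing correction is applied across queries, by design.
* Exact matching after IUPAC expansion: no mismatch tolerance, no
  position-weight-matrix scoring.
* The distance null assumes uniformly placed occurrences on one fixed-length
  region; promoters with strong positional composition biases will deviate
  from it for reasons unrelated to pair spacing.
* The false-candidate rate of the screen depends on the interplay between
  `min_matches`, promoter-set size and the random-motif length range;
  changing one without reconsidering the others changes the calibration.
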