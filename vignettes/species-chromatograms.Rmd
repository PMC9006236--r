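---
title: "Species chromatograms: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Species chromatograms: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichebands)
```

## The model

The Hutchinsonian niche of a species is the set of environmental
combinations in which it can grow, maintain and reproduce — a p-dimensional
hypervolume that is hard to display once p > 3. A species chromatogram
projects it onto a plane without ordination: every environmental gradient
becomes one column of an α × p matrix, standardized onto [0, 1] and cut
into α equidistant categories, and each cell holds the standardized maximal
abundance of the species under those conditions. The niche is read off as
colour bands: band position is the optimum, band width the breadth, and two
chromatograms built with shared standardization can be compared cell by
cell.

The pipeline in `chromatogram()` is:

1. **Row filtering.** Samples with a missing value on any environmental
   dimension are discarded (the count is reported); a missing abundance is
   treated the same way. Zero abundance is *data*, not missingness — a
   dedicated `NA` marker is reserved for categories without an estimate.
2. **Standardization (per dimension).**
   `z* = (z − min) / (max − min)`. When several species are compared the
   (min, max) pair must be pooled over all of them (`shared_env_range()`,
   or the `chromatograms()` wrapper), otherwise category i would mean
   different conditions in different chromatograms; `pairwise_d()` warns
   when it detects ranges that differ. A constant dimension has no gradient
   and raises an error naming the dimension.
3. **Binning.** Category i covers [(i−1)/α, i/α), half-open, with the last
   bin closed at 1, so each value maps to exactly one of the α categories.
4. **Per-category abundance.** A category with at least `m` samples is
   scored with the mean of its `n_top = max(n_top_min, ceiling(k/100 ×
   count))` highest abundance values. Averaging only the top k% is the
   ecological heart of the construction: a sample can sit in a perfectly
   suitable temperature category while salinity is lethal, so low values in
   a category say little about the focal gradient, and only the best
   observed performances approximate the response to it.
5. **Smoothing.** A trailing simple moving average (`smooth_window`,
   default 2; the first window−1 cells are copied) damps
   category-to-category noise. Any window touching a missing category
   yields a missing value, so smoothing can *increase* the number of white
   categories — a deliberate choice: inventing an estimate next to a data
   gap would silently widen bands.
6. **Column standardization.** Each column is divided by its maximum, so
   every dimension's best category scores exactly 1 and abundances become
   comparable across dimensions and species. A column with no positive
   estimate is left entirely missing, with a warning.

## Parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `alpha` | 50 | categories | gradient resolution; more categories need more samples per category |
| `m` | 20 | samples | minimum evidence for an estimate; use 1 for simulated/dense data, 20 for noisy survey data |
| `k` | 5 | % | share of highest abundances averaged per category; small k ≈ max, 100 = plain mean |
| `n_top_min` | 1 | values | floor on the number of values averaged; raise it (e.g. to 4) to always average several values |
| `smooth_window` | 2 | categories | trailing moving-average length; 1 disables smoothing |
| `T` | 0.25 | standardized abundance | cutoff defining which categories belong to the niche for breadth and overlap; at T = 0 the comparison is strict (> 0) so observed absence never counts as presence |

## Optimum and breadth

The **optimum** of a dimension is not the category centre but the mean raw
environmental value of the samples whose abundances produced the maximal
category — a finer estimate than the α-grid allows. Two choices were open:

* *which* samples: the contributors recorded **before** smoothing, because
  smoothing mixes neighbouring categories while the optimum should reflect
  the samples actually observed under the best conditions; the maximal
  category itself is located on the final (smoothed, standardized) column,
  the same surface the user sees;
* *ties*: if several categories share the maximum, their contributor sets
  are pooled — symmetric and robust for plateau-shaped responses.

The **breadth** is `E = (U_max − U_min + 1) / U* × 100`, where U_max/U_min
are the highest/lowest categories with abundance ≥ T and U* is the number
of categories with an estimate. The inclusive count (+1) makes a niche
spanning all categories exactly 100%; the non-inclusive variant
(`span = "printed"`), which tops out at (α−1)/α, is kept for comparison.
Because the span may bridge missing categories, the ratio could
arithmetically exceed 100%; E is capped at 100 so it stays a percentage of
the estimated gradient. `E` is non-increasing in T, and `E_T` (via
`mean_breadth()`) averages over dimensions.

## Overlap index D and the combination scan

For overlap the niche on each dimension is reduced to the contiguous
category interval [U_min, U_max] (`select_and_fill()`): interior categories
below T or without an estimate are filled, assuming a unimodal, continuous
niche, which turns the joint niche into a hyperrectangle on the category
lattice. With interval lengths β (species 1), γ (species 2) and
intersection lengths θ,

D = 100 · V12 / (V1 + V2 − V12),  V1 = Πβ, V2 = Πγ, V12 = Πθ,

the intersection-to-union cell-count ratio. D is symmetric, lies in
[0, 100], equals 100 only for identical filled intervals on every
dimension considered, and can only decrease when a dimension is added
(θ ≤ min(β, γ)). A species with an empty selection on some dimension has
volume 0; D is then defined as 0 with a warning rather than left undefined.
The index can be biased when the lowest or highest selected category is
poorly identified (few samples at gradient ends).

`combination_scan()` enumerates all 2^p − 1 dimension subsets (p ≤ 20 is
enforced; the cost doubles per dimension) and averages the pairwise D
values over the off-diagonal upper triangle. Including the diagonal of
self-overlaps (100s) would shift every subset's mean equally without
changing the ranking; it is excluded by default and exposed via
`include_diagonal`. Ties between subsets are broken lexicographically by
dimension index. The per-size minima are non-increasing in subset size,
which the tests verify against a brute-force lattice enumeration.

## The pseudo-species simulator

`generate_pseudo_species()` creates virtual species whose niches are known
exactly, which is how the pipeline is validated: simulated data have known
distributions and overlaps, while field data carry unknown biases. Each
dimension of a pseudo-species follows the beta response
`A(p) = c · ((p_max − p)/(p_max − p_opt)) · ((p − p_min)/(p_opt − p_min))^q`
with `q = (p_opt − p_min)/(p_max − p_opt)` — unimodal, skewed, zero outside
(p_min, p_max), peaking at exactly c at p_opt. Per-dimension abundances
are **summed** (additive aggregation) over three gradients: env1 from 0 to
25, env2 from 0 to 40, env3 *decreasing* from 1 to 0 (standardization makes
orientation irrelevant). 100 samples per species are placed on an even grid
along each gradient by default — deterministic, so duplicate tables are
bit-identical; a uniform-random mode with an explicit seed exists.

Additivity has a consequence worth spelling out: a pseudo-species is
present wherever *any one* of its responses is positive, so its realized
support along a gradient is the union of all per-dimension supports mapped
through the sampling design. The default seven-species family therefore
aligns each species' supports at the same quantile positions on all three
gradients, so that intended relations hold for the whole species: sp1
(quantiles 0–0.4 everywhere) and sp2 (0.6–1) are exactly disjoint, sp5
contains sp4 with the same optima and exactly doubled amplitude, sp3 is a
full-range generalist. The family is a documented default, not a fixed
truth — any list of `pseudo_species_spec()` tibbles is accepted.

What the simulator does **not** emulate about real survey data: sampling
noise and zero inflation (abundances are exact function values), varying
effort across the gradient, spatial and temporal autocorrelation,
correlated environmental dimensions beyond the sampling design, and
realized-vs-fundamental niche distortions from biotic interactions or
dispersal. Tests passing on pseudo-species therefore demonstrate the
*numerical* correctness of the pipeline, not robustness to survey noise —
the `m` and `k` thresholds exist for the latter and are exercised only
lightly here.

## Numerical choices and degenerate inputs

* Bin edges half-open with the last bin closed; boundary values go to the
  upper bin. Exactness at edges is only guaranteed where the edge is
  floating-point representable.
* `n_top` has a floor of 1 (`n_top_min` raises it) and is capped at the
  category's sample count.
* T = 0 selects strictly positive cells; T > 0 selects `≥ T`.
* Degenerate cases: all-missing dimension → error for optimum/breadth;
  empty selection → breadth 0, overlap volume 0 (D = 0 with warning);
  constant dimension → error at standardization.
* Missing categories inside a filled interval count toward interval length
  — the fill is unconditional.
* Grid matching (`match_env_nearest()`) looks up the nearest coordinate
  per axis (nearest latitude, longitude, day) rather than great-circle
  distance — equivalent on a regular grid and cheap; midway ties go to the
  lower index; dates are matched at daily resolution.

## Problem sizes

The test-suite simulations are sized for seconds, not minutes: oracle
equivalence uses 500 random niche pairs at α ≤ 8, p ≤ 3 against an explicit
cell enumeration; optimum recovery uses one pseudo-species sampled at
2 000 grid points with α = 50, m = 1, k = 100 and no smoothing (isolating
the binning error, which is bounded by one category width); end-to-end
overlap checks use the default 100-sample design at α = 50, m = 1, k = 5,
the configuration under which every category holds two samples and the top
5% rule reduces to the category maximum.

## Limitations

The hyperrectangle assumption ignores niche holes and interactions between
dimensions; D compares boxes, not shapes. Breadth and overlap depend on T,
and on noisy data different thresholds can reorder species. The optimum of
a multimodal response is ill-defined (ties are pooled, which averages the
modes). Chromatograms built with per-species standardization are not
comparable; the package warns but cannot repair this after the fact.
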