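---
title: "Dispersion-based grey relational analysis for panel data: models and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dispersion-based grey relational analysis for panel data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(greypanel)
```

## The problem

Panel data in environmental-loss analytics are three-dimensional: `m`
indicators (or investigation objects), each observed as an `N x n`
behaviour matrix over `N` samples (provinces, stations, cohorts) and `n`
time points. Grey relational analysis (GRA) scores the association
between two such series by the geometric similarity of their data
surfaces rather than by covariance, which suits the short, irregular,
small-sample records typical of disaster statistics: five provinces over
five years is a perfectly ordinary input here.

Surface-based panel GRA, however, has a structural defect. The extended
grey absolute relational (EGAR) model triangulates each behaviour matrix
into a piecewise-linear surface and compares volumes, but every grid cell
can be split along either diagonal, and the two triangulations give
different volumes and hence different relational degrees for the *same
data*. The dispersion-based model (DPGRA) implemented here replaces the
surface geometry with a variance statistic that is independent of cell
connection and of sample/time ordering, restoring uniqueness.

## The DPGRA model

Both panels are first made dimensionless with the average operator `Z`:
each value is divided by the mean of its scope (`mean_normalize()`).
For normalized panels `x_i` and `x_j` the entrywise absolute-distance
field is

&nbsp;&nbsp;&nbsp;&nbsp;`l_ij(s,t) = |x_i(s,t) - x_j(s,t)|`,

its grand mean is `l̄_ij`, and the **dispersion of panel data** is the
population variance of the field:

&nbsp;&nbsp;&nbsp;&nbsp;`D_ij = (1/(N·n)) Σ_s Σ_t (l_ij(s,t) - l̄_ij)²`.

`D_ij = 0` exactly when the two surfaces differ by a constant gap
everywhere — a stable, perfectly parallel relationship — and grows with
the volatility of the gap. The divisor is `N·n`, not `N·n − 1`: the
definition is a population variance, and the implementation follows it
verbatim (`dispersion()` carries the field, its mean and the variance in
one record). The relational degree is

&nbsp;&nbsp;&nbsp;&nbsp;`ε_ij = D̄ / (D̄ + D_ij)`,

which lies in `(0, 1]`, equals 1 iff `D_ij = 0`, and is strictly
decreasing in `D_ij`. `D̄` is a cohort mean of dispersions; it sets the
scale of the ε values but cannot change their ordering, so rankings are a
function of the dispersions alone.

### The cohort-mean conventions

The defining formula `D̄ = (1/m) Σ D_ij` underdetermines both the index
set and the divisor, and the two published analyses this package
reproduces use demonstrably different conventions. `greypanel` makes both
explicit:

* **reference mode** (`dpgra_reference()`): `D̄` is the arithmetic mean
  of the comparison-vs-reference dispersions, self-pair excluded. With
  the six bundled indicator dispersions this gives `D̄ = 3.67475`
  (printed as 3.6747).
* **pairwise mode** (`dpgra_pairwise()`): `D̄` is the sum of the
  `m(m−1)/2` distinct pair dispersions divided by `m(m+1)/2`, i.e. the
  mean over all unordered pairs *including* the zero-valued self-pairs.
  This is the only divisor among the natural candidates (`m`, `m²`,
  `m(m−1)/2`, `m(m−1)`, `m(m+1)/2`) that reproduces the bundled
  five-province degree matrix; with the bundled dispersions
  `D̄ = 121.8908/15 = 8.12605`.

Because `D̄` aggregates over the cohort, ε *magnitudes* are
cohort-relative even though each `D_ij` depends on its two panels only.
Uniqueness and independence therefore hold for the dispersions and for
rankings; they do not hold for ε magnitudes across different cohorts.
The package documents this rather than "fixing" it, since any fix would
change the published numbers.

### A note on the last printed digit

Recomputing the bundled analyses exactly shows that the published
reference-mode degrees were truncated at the fourth decimal (exact
0.713190 and 0.770558 appear as 0.7131 and 0.7705), while the published
pairwise matrix was rounded (one cell, exact 0.310265, appears as 0.3102
— a truncation). Every printed value is within `1e-4` of exact
arithmetic, and the acceptance tests assert at that printed precision.
The package itself always computes and stores full-precision values;
4-decimal strings appear only in display columns.

## The EGAR model and its non-uniqueness

`signed_volume()` sums, over all `(N−1)(n−1)` unit cells of a zero-point
image (each row shifted so its first value is zero,
`zero_point_image()`), one of two corner weightings:

* style 1: `(1/3)(A2 + A3) + (1/6)(A1 + A4)`
* style 2: `(1/6)(A2 + A3) + (1/3)(A1 + A4)`

where `A1..A4` are the corner values at `(s,t)`, `(s+1,t)`, `(s,t+1)`,
`(s+1,t+1)`. The two styles are the two diagonal choices of the cell
triangulation. The degree is
`ε = (1 + |s_i| + |s_j|) / (1 + |s_i| + |s_j| + |s_i − s_j|)`, with
absolute values applied to the *whole-panel* signed sums and the
difference volume accumulated corner-wise inside the sum before the
absolute value. The discrete weighted sums are taken as the operative
definition throughout; no continuous-interpolant integral is
reconciled against them. `uniqueness_gap()` reports
`|ε_style1 − ε_style2|`: it is zero exactly when both zero images vanish
(every row of both panels constant in time) and is positive on
essentially every generic input — the defect, reproduced on demand, that
motivates the dispersion model.

```{r egar-demo}
img <- matrix(c(0, 1, 0, 0), 2)     # one cell, corner A2 = 1
egar_from_images(img, matrix(0, 2, 2), style = 1)$degree  # 0.8
egar_from_images(img, matrix(0, 2, 2), style = 2)$degree  # 0.875
```

## Tunable parameters

| parameter | where | default | why |
|---|---|---|---|
| `scope` | `mean_normalize()` | `"row-mean"` | each sample's time series is a sequence in its own units; per-row scaling neutralizes heterogeneous units (yuan, persons, counts) across rows of an object matrix. `"matrix-mean"` is offered for panels whose rows share units. The published analyses do not record which scope produced their dispersion tables, so the default is a documented choice, not an asserted reproduction. |
| `zero_row_policy` | `mean_normalize()` | `"zeros"` | an identically-zero series (a death toll that never moved) has no mean to divide by; mapping it to an all-zero normalized row keeps the pipeline running and preserves the qualitative result that such a series is maximally dissimilar from a fluctuating reference. `"error"` is available for datasets where a zero row indicates corruption. |
| `mode` | degree stage | per analysis | `"reference"` for one-vs-many indicator studies, `"pairwise"` for all-pairs object studies; the two cohort-mean conventions above. |
| `tie_policy` | `rank_series()` | `"competition"` | ties share the smallest rank with stable input order; `"average"` gives mid-ranks. The bundled analyses contain no ties. |

Floating-point equality uses absolute tolerance `1e-9` internally (e.g.
symmetry and zero-diagonal validation of ingested dispersion matrices);
display rounds to 4 decimals to match the published tables.

## What the synthetic generator emulates — and what it does not

`generate_panel_set()` builds a positive reference series (log-normal
sample levels around `offset`, linear trend, sinusoidal seasonal term)
and comparisons `scale_j · (reference + N(0, σ_j))`, clipped at a small
positive floor. The noise is injected *before* the uniform rescale: mean
normalization removes the rescale exactly, so the effective noise
ordering across comparisons is exactly the `σ` ordering, `σ_j = 0`
yields a perfectly related comparison (`ε = 1`), and rank-recovery
experiments have a known ground truth. Designated zero series are
emitted as all-zero matrices to exercise the zero-row policy.

`generate_storm_tide_like()` fixes the shape of a coastal disaster-loss
panel — 7 series × 5 provinces × 5 years, indicator magnitudes spanning
more than three orders, log-normal (heavy-tailed in level) fluctuations,
one identically-zero death-toll analogue — with a shared storm-season
year signal so that loss indicators co-move the way physically coupled
indicators do.

The generators do **not** simulate storm-surge physics, spatial
correlation between provinces, reporting artifacts, or the actual loss
distributions behind the bundled dispersion tables. A green test on
synthetic data therefore establishes that the estimator recovers *known
constructed structure* (ordering, invariances, degenerate cases); it
does not validate the substantive storm-tide conclusions, which rest on
the published dispersion tables ingested as data.

The rank-recovery experiment is fixed a priori at a geometric noise
ladder `σ = (0.5, 1, 2, 4, 8)` against a reference of median level 10 —
5 % to 80 % relative noise in factor-of-two steps, the separation a
simulation study would call "well-separated but overlapping" — with
`N = n = 10` and 200 seeded replicates, requiring exact recovery of the
full 5-series ordering in at least 95 % of replicates.

## Numerical and design choices

* **Degenerate cohort**: if every dispersion in the cohort is zero,
  `D̄ = 0` and `ε = D̄/(D̄ + 0)` is `0/0`; the degree is defined as 1
  (all pairs perfectly related), the only continuous completion.
* **Zero-point image**: the transform is `x(s,t) − x(s,1)` per row — the
  standard absolute-GRA convention; it makes the "both images vanish"
  equality condition of the two EGAR styles coincide with
  "per-row-constant raw panels", which is unit-tested.
* **Ordering sensitivity**: the dispersion statistic is invariant under
  any simultaneous permutation of samples and of time points (it sees
  the distance field as a bag of values); the EGAR surface is not, since
  permutations change cell adjacency. Both facts are unit-tested, and
  the reader ingests labels as opaque strings in file order.
* **Strict iff**: `ε = 1` exactly when the distance field is constant,
  which includes constant-offset normalized panels, not only identical
  ones. This is slightly stronger than the usual one-directional
  normativity statement and is asserted in both directions by the tests.
* **Wide layout**: "one file per series" CSVs; spreadsheet sheets are
  out of scope. The long layout (`series, sample, time, value`) is
  canonical and validated for duplicate triples and missing cells with
  row-level error messages.
* **YAML config**: omitted; no YAML parser is available in the target
  environment's R stack and every option is reachable as a CLI flag.

## Known limitations

* ε magnitudes are not comparable across cohorts with different `D̄`;
  only rankings and the dispersions themselves are.
* The dispersion is a variance of *absolute* distances: antisymmetric
  disagreements (one series above, then below) and one-sided volatile
  gaps of equal variance are indistinguishable.
* No significance testing or uncertainty quantification is attached to
  ε; the model is descriptive.
* The bundled tables are published *dispersions*; the raw loss panels
  behind them are not redistributed, so the normalization scope used to
  produce them cannot be verified from within this package.
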