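---
title: "Methods: cumulative drinking-water cancer risk and demographic disparity screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cumulative drinking-water cancer risk and demographic disparity screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Community water systems (CWS) in the United States monitor a panel of
carcinogenic contaminants — arsenic, nitrate, radionuclides, disinfection
byproducts — and report results per system under a public water system
identifier (PWSID). Service-area GIS layers locate the population each
system serves, and census tracts carry demographic composition. This
package chains the three into a screening analysis: per-system cumulative
cancer risk, area-weighted demographic attribution, cohort filtering, and a
nonparametric trend test of risk across demographic terciles. It runs
end-to-end on synthetic data so that every statistical property of the
chain can be tested; real monitoring tables, service-area polygons and
tract layers in the same schemas drop straight in.

## Cumulative cancer risk

For each system, the long-term average concentration $C_i$ of contaminant
$i$ is the arithmetic mean of all test results in the study window
(default 2014-01-01 to 2019-12-31), with non-detects substituted as zero
before averaging. The cumulative risk statistic is the hazard sum

$$R = \sum_{i=1}^{N} \frac{C_i}{B_i},$$

where $B_i$ is the contaminant's cancer-risk benchmark: the concentration
corresponding to a $10^{-6}$ lifetime cancer risk. $R$ (`rho` in the code)
is therefore expressed in units of $10^{-6}$ lifetime risk, and
`lifetime_risk` $= \rho \times 10^{-6}$.

Decisions that shape this statistic:

* **Non-detects are zero.** Substituting zero (rather than half the
  detection limit) biases means low for heavily censored contaminants but
  adds no fabricated mass; it is the convention the statistic was designed
  around, and offering a silent alternative would change results
  invisibly. No other censoring rule is implemented.
* **Absence is not zero.** A contaminant never tested at a system is
  *absent* from its profile, not present at zero: absence of testing is
  not evidence of absence. Occurrence summaries count "systems with data"
  accordingly.
* **Units.** Each contaminant's canonical unit is its benchmark's unit.
  Mass units interconvert (1 mg/L = 1000 µg/L = 10⁶ ng/L); pCi/L is an
  activity unit and any attempt to mix it with mass units for one
  contaminant is an error, never a silent conversion.
* **Haloacetic-acid groups.** The grouped parameters HAA5 and HAA9 (the
  nine-acid group contains the five-acid group) can both be measured for
  one system. When both are present, only the HAA9 term enters the risk
  sum; a system with only HAA5 keeps it. No risk result can ever carry
  both terms.
* **Benchmarks are configuration.** The $B_i$ table is user-supplied
  (YAML/JSON). The values shipped under `inst/extdata/` are illustrative
  placeholders for the synthetic demo, not published health guidelines.
* **Duplicates are retained.** Identical records (same system,
  contaminant, date, value) all enter the mean — every available test
  result counts.

## Areal attribution of demographics

Tract-level counts are apportioned to each service area by the fraction of
the *tract's* area covered:

$$Y_{CWS} = \sum_t \mathrm{frac}_t \cdot Y_t, \qquad
  \mathrm{frac}_t = \frac{\mathrm{area}(\mathrm{tract}_t \cap \mathrm{system})}{\mathrm{area}(\mathrm{tract}_t)},$$

assuming population is evenly distributed within each tract. The default
("counts") mode apportions population and subgroup *counts* and derives
percentages from the sums — the only mode that conserves total population
when systems partition a region. A "percent" mode (area-fraction-weighted
average of tract percentages) is kept behind a flag for sensitivity
analysis, because the attribution equation is often written generically
over "the demographic variable", which is ambiguous between the two
readings.

Geometry handling is deliberately minimal and explicit:

* All geometries must arrive in one planar, equal-area coordinate system;
  the package validates planarity assumptions but never reprojects
  (real-data users reproject upstream; synthetic data is born planar).
* Intersection areas are computed with an in-package Sutherland–Hodgman
  clipping routine (shoelace areas), which is exact when the *source zone*
  (the tract) is convex. Tracts must therefore be single convex polygons —
  always true for the synthetic grid. Service areas may be concave,
  multi-part geometries. Non-convex tracts and rings with holes are
  rejected rather than silently mis-measured; the test suite checks the
  clipping against an independent point-sampling oracle.
* A sliver tolerance of $10^{-9}$ of the tract area suppresses
  floating-point sliver intersections; fractions are capped at 1.
* Invalid geometries are rejected, not auto-repaired — repair changes
  areas.

## Cohort filtering

Risk and attribution tables join by PWSID (inner join, with both
unmatched counts reported — no system disappears silently). Inclusion
rules then apply in a fixed order, each exclusion recorded with its first
failing rule so the ledger is deterministic:

1. non-community systems (only when a `system_type` column is present);
2. wholesale systems — a reported served population of zero;
3. systems serving 500 or fewer people;
4. systems whose tract-assigned population is outside ±50% of the
   reported population (the band is inclusive: ratios of exactly 0.5 and
   1.5 pass).

Size classes follow the service-population convention: very small ≤ 500,
small 501–3300, medium 3301–10,000, large 10,001–100,000, very large
> 100,000. The small class's lower bound is set at 501 so that the class
partition aligns exactly with the "> 500 people" inclusion floor (published
tables sometimes print the small class as starting at 500; the two
conventions differ only in how the boundary value is displayed, since
systems at exactly 500 are excluded anyway).

## Tercile trend analysis

Within each analysis stratum (the whole cohort, and each size class when
stratified), systems are sorted by the subgroup percentage — ties broken
by PWSID so the split is deterministic — and cut into three contiguous
groups whose sizes differ by at most one; remainders go to the lowest
tercile(s) first. Each tercile reports its boundaries (min/max
percentage), system count, total reported population, and median lifetime
risk (midpoint-of-order-statistics median).

The monotone-trend test is a from-scratch Jonckheere–Terpstra test:

$$J = \sum_{k<l} \Big[ \#\{x \in G_k, y \in G_l : x < y\}
      + \tfrac12 \#\{x = y\} \Big],$$

with null mean $\mu_0 = (n^2 - \sum_k n_k^2)/4$ and the tie-corrected
Hollander–Wolfe null variance, which reduces to
$[n^2(2n+3) - \sum_k n_k^2(2n_k+3)]/72$ without ties. P-values come from
three interchangeable methods: the asymptotic normal approximation on
$z = (J-\mu_0)/\sqrt{\mathrm{var}_0}$ (no continuity correction), exact
enumeration of all equally likely group assignments (total $n \le 10$,
where the support is small), or a seeded Monte-Carlo permutation null
(default $10^5$ draws). `method = "auto"` picks exact for $n \le 10$ and
asymptotic otherwise. A degenerate sample (all values equal) returns
$z = 0$, $p = 1$. Sidedness is configurable and recorded in every report;
the default is two-sided, since published analyses of this kind rarely
state sidedness and the conservative default avoids overclaiming.
Strata with fewer than 6 systems report terciles but skip the test with an
explicit reason — three groups of one or two observations cannot support
any of the three methods meaningfully. No multiple-testing correction is
applied across strata; the number of tests performed is visible in the
report so users can adjust externally.

## The synthetic study region

The generator emulates the *structure* of the real inputs, not US
geography:

* **Tracts**: an `n_x × n_y` grid of square tracts (side 1000 m by
  default) tiling a rectangle; populations uniform on 1200–8000 (the
  typical census-tract range); subgroup fraction per tract from
  Beta(2, 2) by default — symmetric, mildly concentrated around 0.5.
* **Systems**: contiguous blocks of 2–5 free cells grown from random
  anchors; cells are never shared, so a partitioned region conserves
  population exactly. With probability 0.3 the last cell enters as a half
  cell, producing overlap fractions strictly between 0 and 1. Reported
  populations are the tract-derived covered population with 15% relative
  Gaussian noise (floored at zero), so the ±50% agreement filter has
  realistic work to do; an optional fraction of systems is stamped with a
  reported population of zero to emulate wholesale systems.
* **Tests**: per system and contaminant, 4–12 records with concentrations
  from a lognormal — non-negative, right-skewed, the standard model for
  environmental concentrations — whose log-mean is
  `meanlog + effect_size · f`, where `f` is the system's subgroup fraction
  from exact areal attribution. Values below the detection limit are
  emitted as non-detects. `effect_size = 0` is the null model: risk is
  independent of demographics by construction.

What the generator does *not* emulate: spatial autocorrelation of
demographics beyond the block structure, non-convex or nested tract
geometry, seasonal or trending concentrations, correlated contaminants,
and reporting artifacts (unit mix-ups, duplicated uploads). Passing tests
therefore demonstrate the correctness and calibration of the *machinery*,
not the robustness of conclusions drawn from any real data set.

## Numerical and reproducibility choices

* Every stage derives its RNG stream from the config seed with fixed
  offsets, so each stage is individually reproducible and the pipeline is
  byte-deterministic: the same config and seed give identical CSV/GeoJSON
  output digests, which the run manifest records along with per-stage
  record counts that must reconcile (matched = included + excluded).
* Exact tercile ties are resolved by PWSID; permuting input row order
  changes nothing.
* The exact-enumeration cutoff ($n \le 10$) and the default permutation
  count ($10^5$) balance fidelity against desk-scale runtime.
* Calibration problem sizes: the type-I simulation uses 10,000 cohorts of
  300 systems drawn from the generator's system-level null model (the
  Beta subgroup fraction and lognormal mean-risk draws are independent
  when `effect_size = 0`, so the system-level sampler is distributionally
  identical to running the full geometry each time); the power study runs
  200 full end-to-end replicates at 40 systems each with the effect sized
  to span four log-standard-deviations across the subgroup range.

## Known limitations

* Convex-tract restriction in the overlay (see above); real tract
  polygons are frequently non-convex and must be pre-decomposed or the
  overlay replaced with a full polygon-clipping backend.
* Zero-substitution for non-detects is the only censoring rule; analyses
  sensitive to censoring should treat the risk sums as lower bounds for
  heavily censored contaminants.
* Tract-based attribution is known to be unreliable for systems serving
  ≤ 500 people (they are excluded by design); block-level data would be
  needed below that scale.
* The trend test detects monotone location shift across terciles; it is
  not a regression adjustment and makes no claim about confounders.
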