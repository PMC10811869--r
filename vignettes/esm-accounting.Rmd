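---
title: "Equivalent-soil-mass SOC accounting: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equivalent-soil-mass SOC accounting: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esmsoc)
```

## Why fixed-depth stocks mislead

A soil layer's fixed-depth (FD) stock multiplies carbon concentration,
bulk density and thickness: $S_{FD} = c\,\rho\,d \cdot 0.1$ Mg C ha$^{-1}$
($c$ in g C kg$^{-1}$, $\rho$ in g cm$^{-3}$, $d$ in cm). The sampled soil
mass $M = 100\,\rho\,d$ Mg ha$^{-1}$ therefore changes whenever $\rho$
changes. Comparing two sampling times on a fixed geometric interval then
compares *different amounts of soil*: a surface that loosened by 16%
exports a sixth of its mass (and the carbon in it) below the interval
bottom, so FD understates a gain; a compacted surface imports extra soil
and FD can report a gain while carbon is actually being lost.

Equivalent-soil-mass (ESM) accounting instead reports the carbon held in a
fixed **reference mass** of soil per layer. `reference_masses()` defines it
as the t0 layer mass averaged over a treatment's replicate plots, shared by
both times and all replicates; ESM layers keep the t0 depth interval as
their "ESM depth" label. A user-supplied reference table is accepted
wherever one exists (e.g. from a published archive), via the `refs`
argument of `stocks_pipeline()`.

## The two ESM engines

**Cumulative-coordinate spline.** Each profile becomes a curve of
cumulative stock against cumulative mass through the knots
$(0,0), (M_1, S_1), (M_1{+}M_2, S_1{+}S_2), \dots$ A natural cubic spline
(zero second derivative at both ends) is fitted through the knots and
evaluated at the cumulative reference masses; layer stocks are successive
differences. Evaluation at a knot reproduces the knot exactly, so a
profile whose sampled masses equal the references returns the FD stocks to
machine precision — the identity every engine must satisfy.

**Classical cascade.** Layers are processed top-down, comparing cumulative
sampled mass with cumulative reference mass. A surplus removes the excess
mass valued at the layer's own concentration; a deficit borrows the
missing mass from the next deeper layer at that deeper layer's
concentration. The two engines agree within about 2% on smooth profiles;
the package computes both so the agreement can be checked per dataset
rather than assumed.

**Extrapolation.** When a column's total sampled mass falls short of the
deepest cumulative reference mass, interpolation would have to extrapolate.
The default is an error stating the shortfall in Mg ha$^{-1}$ — the
conservative reading of "sample deeper than the target mass". With
`extrapolate = TRUE` the last spline segment is extended linearly (the
natural spline is linear beyond its end knot) and, symmetrically, the
classical cascade values a deepest-layer deficit at the deepest measured
concentration; affected layers are flagged in the output. The override
matters in practice: references are treatment *means*, so about half of
all replicate columns sample slightly less than the reference even with no
systematic change, and any surface loosening shifts whole treatments below
it. Without the override the method would be unusable on exactly the data
it is designed for.

**Spline overshoot.** Interpolating a non-smooth truth can produce small
negative layer stocks. These are reported as-is with a warning rather than
clipped: clipping would silently bias the cumulative sums that downstream
statistics consume.

### Accuracy against brute force

The test suite checks the spline engine against a 0.05-cm discretisation
of smooth underlying fields (bulk density saturating with depth,
concentration decaying exponentially to a floor, depth scales 40–90 cm):
layer means are handed to the engine, the fine integration provides the
truth, and agreement is required within 0.5% of the cumulative stock at
queries 2–8% below each knot mass. Against a *piecewise-constant* column
the benchmark itself is kinked at every boundary — no smooth interpolant
can do better than about 1% there, and the tests assert exactly that
weaker bound. This distinction is worth remembering when interpreting ESM
stocks computed from coarse increments: the spline's accuracy claim is
about smooth underlying profiles, not about literal step functions.

## Change statistics

`change_stat()` compares replicate values at the two times with a Welch
(unequal-variance) two-sample $t$: mean change, CI at the requested level,
$t$, Satterthwaite df, $p$, and percent change relative to the t0 mean.
Hedges' $g$ uses the pooled SD with the small-sample factor
$J = 1 - 3/(4(n_0{+}n_1{-}2)-1)$, even though the test is Welch — the
conventional pairing in effect-size reporting. Zero variance in both
groups with equal means returns the $g{=}0$, $p{=}1$ convention; with
unequal means it is an error, not a silent infinity. No multiple-testing
adjustment is applied anywhere; rows are reported one at a time as in the
tabular outputs they mirror.

`method_contrast()` compares the per-plot stock changes under ESM and FD;
its `diff = ESM − FD` is the error attributable to fixed-depth accounting
when ESM is taken as correct. The default is an unpaired Welch test with a
`paired` option: the plots coincide, but the dispersion of the two change
vectors is dominated by the same plot-level noise, and both variants are
exposed because the choice is genuinely open.

`required_sample_size()` iterates the noncentral-$t$ power condition for a
two-sided two-sample test of a relative change against a coefficient of
variation; it is cross-checked in the tests against `stats::power.t.test`
and a brute-force simulation. At 30% CV, detecting a 10% change with 80%
power needs 143 replicates per group — the quantitative reason deep-layer
change detection is hard.

## Attributing the FD error to bulk density

For each plot, `bd_stock_delta()` prices the soil mass gained or lost
through the bulk-density change over the top 30 cm at the t1
concentration: $\sum (\rho_{t1}-\rho_{t0})\,d \cdot 100 \cdot c_{t1}/1000$.
`association_records()` pairs it with the gap between the t1 FD and t1 ESM
stocks over the same layers, and `association_r()` reports the Pearson
correlation. The gap is oriented FD − ESM so that loosening drives both
quantities negative and compaction both positive (an orientation flag
flips it); the two surface layers are summed into one record per plot,
with treatments pooled within an experiment.

## Crediting

`lcl_difference_between_means()` implements the empirical-sampling
crediting bound: the lower end of the two-sided 50% Welch CI on the
difference between t0 and t1 means — equivalently a one-sided 75% lower
bound, so a no-change field receives credits only 25% of the time (the
test suite verifies 25% ± 1.5% over 10,000 null draws). The alternative
`lcl_mean_difference()` is the one-sample bound on paired differences at a
two-sided 90% level. Credits convert at exactly 44/12 t CO₂e per Mg C and
`issue_credits()` floors the field total to a whole number, never below
zero. Flooring is the conservative choice; published crediting tables are
internally inconsistent on half-credit cases, so the package picks the
rounding that cannot over-credit. `credit_table()` credits each depth
increment separately and also the 0–30 and 0–60 cm aggregates, and marks
layers whose mean bulk density moved more than 5% — FD rows there carry an
explicit note recommending ESM. Only a static baseline is implemented:
credits measure change against the t0 measurement, not against a
business-as-usual counterfactual.

## What the generator emulates — and what it does not

`preset()` encodes three study regimes and a constructed null:

* `century_maize_like` (n = 6; increments 0–15, 15–30, 30–60, 60–100,
  100–200 cm): surface BD −16%, surface concentration +41%, the
  organic-amendment regime where FD understates gains. Baseline BD
  1.44–1.62 g cm$^{-3}$, surface concentration 9.8 g C kg$^{-1}$ decaying
  with an 80-cm scale — a low-carbon irrigated silt loam.
* `century_wheat_like`: same soil, BD −15% with only a small concentration
  rise.
* `wicst_like` (n = 12; increments to 90 cm): surface BD +19% with
  concentration −8% on a carbon-rich Mollisol (surface 25 g C kg$^{-1}$,
  40-cm decay scale) — the no-till compaction regime where FD reports a
  gain while ESM correctly shows the loss.
* `compaction_null`: each replicate's t1 column is its own t0 column with
  layer masses multiplied by (1.15, 1.08, 1.03, 1, 1) and the mass-ordered
  concentration carried over unchanged, so the true ESM change is zero by
  construction while FD inflates.

Noise is Gaussian, independent across layers and replicates, with draws
below physical bounds resampled. Two deliberate structural choices:
deep-layer SDs are larger than surface SDs, reproducing the growing spread
of stock estimates with depth that makes deep change detection hard; and
the t0 SDs are smaller than the t1 SDs, because these long-term trials
began from a deliberately uniform baseline (a single crop planted across
the whole site before plot layout) while two decades of plot-specific
management response disperse the plots far beyond the baseline spread.
The SD magnitudes were set once from the published CI widths and effect
sizes of the emulated experiments (e.g. a surface BD change CI of roughly
±0.07 g cm$^{-3}$ at n = 12, concentration-change CIs of ±1.1 g C kg$^{-1}$
at n = 6).

What passing tests on these synthetics do **not** show: the generator has
no spatial autocorrelation, no block effects, no covariance between bulk
density and concentration errors, no measurement-method bias between
campaigns, and no mechanistic carbon turnover. Results on real data will
additionally reflect all of those; the synthetics establish that the
accounting arithmetic, the statistics and the crediting rules behave
correctly, not that any field will match the presets.

## Numerical and interface choices

* Depth increments are half-open `[top, bottom)` cm, positive downward,
  contiguous from 0; duplicate or gapped increments are validation errors
  naming the plot and boundary.
* Increment remapping (`remap_increments()`) is overlap-weighted averaging
  of intensive quantities, generalising the two-adjacent-increment
  weighted average used to harmonise historical sampling grids; it
  conserves mass exactly and is linear in the field values. Stocks are
  never remapped — they are recomputed from remapped intensive fields.
* CSV I/O is comma-delimited UTF-8 with "." decimals; doubles are written
  with 17 significant digits so read–write–read is bit-exact. Missing
  values in required numeric columns are rejected.
* All tabular outputs have fixed column orders; rerunning a pipeline on
  identical input yields identical files. `run_all()` writes a JSON
  manifest recording options and package version.
* Problem sizes in the tests — 25 randomized spline-oracle profiles,
  10,000 null crediting draws, 200 generator seeds for parameter recovery,
  coverage checks at n = 6 — were chosen as the smallest sizes at which
  the Monte-Carlo error is clearly below the tolerance being asserted.

## Known limitations

* The classical cascade assumes one sampled layer per ESM layer; profiles
  remapped to a different grid must be harmonised first.
* Spline extrapolation beyond the sampled mass is linear and flagged, but
  still extrapolation; deficits much larger than the deepest layer's mass
  deserve resampling, not correction.
* Hedges' g on Welch tests mixes a pooled-SD effect size with an
  unpooled test; with strongly unequal variances interpret g cautiously.
* Crediting is per-field and static-baseline; no buffer pools, permanence
  discounts, or counterfactual comparisons.
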