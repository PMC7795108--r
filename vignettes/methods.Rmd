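---
title: "Methods: three-level medical accessibility and equity on gridded demand"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: three-level medical accessibility and equity on gridded demand}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medaccess)
```

## Overview

`medaccess` evaluates how conveniently residents of a gridded study area
reach medical services at three levels of care, and how fairly that
convenience is distributed over space and over population groups. The
analysis chain is: transport graph → origin–destination (OD) travel
costs → six accessibility surfaces → spatial autocorrelation → equity
statistics → parameter sensitivity. This vignette documents the models,
their assumptions, the tunable parameters, the synthetic data generator,
and the numerical and design choices that were genuinely open.

## Travel costs: improved node-cost network analysis

Demand cells and facilities rarely sit exactly on a digitized road, so a
plain shortest-path cost misses the off-network *access legs*. The
node-cost approach adds them: each endpoint snaps to the nearest point
on a non-rail edge, and the leg is costed by a two-speed rule with a
walking regime within `d_threshold` and a feeder regime beyond it.

* `d_threshold` = 1250 m — the distance walkable in 15 min at
  `walk_speed` = 5 km/h. Beyond it the leg uses `feeder_speed` =
  25 km/h, standing in for the low-class roads that digitized provincial
  networks systematically omit.
* Class design speeds (km/h): national 80, provincial 70, county 50,
  township 25, special 20, village 15, high-speed rail 200, ordinary
  rail 120. Edge time is `length / speed`.

Omitted low-class roads also produce spurious detours: two nearby points
may be joined only through a long network loop. The package therefore
evaluates two candidates and keeps the cheaper:

* **network**: `leg(origin) + shortest path + leg(destination)`;
* **direct**: the straight-line origin–destination distance costed by
  the same two-speed rule (time metric) or as raw meters (space metric).

The published formulation states a conditional — use the Euclidean
distance when it costs less than the endpoint-to-network legs — which is
weaker and ambiguous about whether the comparison uses the sum or the
larger of the two legs. We implement the stronger `min(network, direct)`
rule as the default: it subsumes the conditional under either reading,
is monotone, and never worsens a cost. The literal conditional (sum
reading) and the plain node-cost result are retained as
`rule = "conditional"` and `rule = "node"` for comparison. Disconnected
pairs fall back to the direct candidate rather than infinity, mirroring
the motivation that disconnection is a digitization artifact.

Snapping inserts *virtual vertices* so paths may start and end mid-edge;
otherwise endpoint granularity dominates small networks. Rail edges are
traversable but never snapped to (boarding happens only where rail and
road share a node), with no boarding penalty — the simplest connected
model in the absence of schedule data. The time metric is interpreted as
*relative* accessibility under current transport; the space metric
(meters, speeds ignored everywhere) as *absolute* accessibility when
transportation is lacking.

A note on the triangle inequality: the plain node-cost satisfies
`Cost(a,c) ≤ Cost(a,b) + Cost(b,c) + 2·leg(b)` (concatenation through
`b` is itself a candidate route), and the improved rule can only lower
the left side further; however the improved costs themselves do not
decompose that way because direct candidates need no legs. The test
suite asserts the provable form.

## The six surfaces

Let `D_k` be cell population, `S_j` facility staff, `P_j` the capacity
weight (2 for tertiary hospitals, else 1), `d_ij` the OD cost, and
`W(d) = max(d, ε)^(-β)` the power-law distance decay.

**Primary (`Pri_T`, `Pri_S`)** — nearest cost, `min_k Cost(i,k)` over
*all* facilities: for common conditions every institution can serve, and
only proximity matters. Lower is better; units are minutes or meters.

**Secondary (`Sec_T`, `Sec_S`)** — two-step floating catchment area over
the secondary + tertiary subset: each facility's supply–demand ratio
`R_j = S_j P_j / Σ_{k: d_kj < d0} D_k W(d_kj)` captures congestion, then
each cell sums the decayed ratios it can reach,
`Sec_i = Σ_{j: d_ij < d0} R_j W(d_ij)`. Defaults: `β = 1` (facility
attraction outweighs distance friction at this tier), `d0` = 120 min or
10 km (the two-hour travel and walking ranges — deliberately generous
for a province-scale area where remote residents must travel far).
Because both steps share the threshold and decay, total delivered
accessibility is conserved: `Σ_i D_i Sec_i = Σ_j S_j P_j` whenever every
facility's catchment contains demand. The test suite checks this
identity to 1e-10 on random instances; one corollary worth knowing is
that the *population-weighted mean* of the surface is then invariant to
`d0`, so threshold sensitivity shows up in the unweighted distribution
statistics (percentiles), not in the weighted mean.

**Tertiary (`Ter_T`, `Ter_S`)** — for serious conditions residents use
tertiary hospitals in their own city or in the provincial capital, rail
included, and tolerate any travel cost; accordingly there is no `d0` and
the surface is the sum of two gravity terms: an own-city term (weight 1,
exponent `β1 = 1.5`, competition restricted to the city's own cells) and
a capital term (weight 2, exponent `β2 = 1`, competition from the whole
region). Cities without a tertiary hospital contribute a zero own-city
term. Two readings were open:

* For capital residents the printed equations make capital hospitals
  contribute through *both* terms. We implement that as printed, with
  `suppress_capital_own = TRUE` available to drop the duplicated
  own-city share.
* The capital term's competition pool is "the whole province", but the
  exponent used inside that denominator is unstated; we use `β2` for
  both numerator and denominator of the capital term (single-exponent
  reading), which preserves the conservation structure of the term.

## Numerical choices

* **Distance floor** `ε` (1 min / 1000 m): `d^(-β)` diverges as
  `d → 0` and co-located supply and demand are common on a grid; the
  floor caps the weight without reordering contributions beyond `ε`.
  Set in the same units as the metric.
* **Strict threshold** `d < d0`, so boundary ties are excluded, matching
  the set notation of the catchment definition.
* Zero-population cells remain demand points with `D = 0`: they receive
  accessibility values (the output maps cover them) but contribute
  nothing to denominators, and they carry no mass in Lorenz accumulation.
* Facility catchments without demand yield `R_j = 0` with a logged
  message rather than an error (real prefectures can have them).
* Constant surfaces are degenerate for Moran's I (zero variance) and for
  reciprocal normalization; both fail or log explicitly rather than
  returning NaN.
* Node de-duplication during network construction rounds coordinates to
  millimeters; snap parameters are kept at full precision so split-edge
  lengths sum exactly.
* Lorenz sorting breaks ties by unit id; the Gini is the trapezoid-rule
  area complement, which equals the population-weighted
  mean-absolute-difference formula to floating precision (tested).
* Percentiles use the nearest-rank convention on unweighted cell values
  (distribution tables describe cells); a population-weighted variant is
  available behind a flag.

## Spatial autocorrelation

Global Moran's I follows the classical cross-product form; its
permutation null is conditional randomization (values shuffled across
units) with a one-tail pseudo p-value in the direction of departure from
`E[I] = −1/(n−1)`. Local Moran's I is `I_i = z_i Σ_j w_ij z_j` with `z`
standardized by the population (n-divisor) standard deviation, so that
`mean(I_i) = I` exactly under row-standardized weights — an identity the
tests assert to 1e-10. LISA labels (HH/LL/LH/HL) are assigned by the
sign pattern of `(z_i, lagged z_i)` among units passing conditional
permutation at `α`.

The source analysis reports grid-scale Moran's I and LISA maps without
stating its weights scheme, permutation count or significance level. We
declare defaults rather than infer them: queen contiguity on the demand
grid, row-standardized; 999 permutations and `α = 0.05` for standalone
use (the bundled pipeline uses 199 to keep end-to-end runs fast); seeds
recorded in every output. Per-subdivision analyses rebuild weights
within the subdivision's cells instead of masking the regional matrix,
because the subdivisions are analyzed as separate study areas. For cost
(`Pri`) surfaces LISA labels are reported on raw costs, so LL clusters
mean *good* access.

## Equity statistics

Cost surfaces are made "higher = better" before Lorenz/Gini by taking
reciprocals and min–max normalizing
(`y = (1/x − min 1/x) / (max 1/x − min 1/x)`); index surfaces enter raw.
Correlation and composition analyses use raw surfaces, so signs are
interpretable (a positive correlation between a group share and a cost
surface means deprivation). County values are population-weighted means
of cell values. Composition tables bin cells by surface percentile —
population-weighted bin edges by default (each decile holds 10% of
people; whether the original figure binned people or cells is unstated,
and cell-count binning is exposed as an option) — and report the group
vs complement share in each bin plus a top-10% readout, where group
segregation is most visible.

## The synthetic study region

The generator emulates the structure the analysis depends on, not any
real geography:

* square grid of `cell_km` = 5 km cells over `extent_km` = 150 km
  (900 cells — about a ninth of a large province at full resolution,
  chosen so that travel costs span the tens-of-minutes to >2 h range in
  which the catchment threshold actually binds);
* `n_cities` = 5 cores sampled at least two cells apart (distinct
  centers on small grids), the first being the provincial capital;
* population 4 million with `rural_fraction` = 0.4 placed as a decaying
  kernel (e-folding one cell) around core centers and a uniform
  low-intensity rural field — the core–periphery contrast every
  downstream equity statistic depends on;
* binomial aging and agricultural strata with core/rural shares
  0.12/0.09 and 0.15/0.70: aging populations concentrate in better-off
  urban counties, agricultural populations in the periphery;
* facilities 230/30/9 (primary/secondary/tertiary), preserving
  realistic per-cell densities; primary placed proportional to
  population everywhere, secondary in core cells, tertiary only in core
  cells with the first in the capital and the rest spread round-robin;
  staff drawn log-normally with level-dependent location (medians 30 /
  150 / 800, `sdlog` 0.4) — capacity distributions are never published,
  so this is an explicit stand-in exposed in the configuration;
* roads: national-class minimum spanning tree over the cores, optional
  extra provincial links, a township/village lattice every other
  centroid line (so ≥90% of cells lie within one cell of a road),
  county connectors from each core, and one ordinary-rail line chaining
  the cores through the capital.

Everything is deterministic given `(config, seed)`, and integer
population allocation uses largest-remainder rounding so totals conserve
exactly.

What the generator does *not* emulate: terrain barriers (mountain
ranges that sever subdivisions), heterogeneous road quality within a
class, capital-heavy tertiary concentration (hospitals are spread evenly
across cores, where real provinces concentrate them in the capital),
commuting behavior, or facility-level service differentiation beyond
staff counts. Consequently, passing tests demonstrate that the *methods*
behave correctly and that the qualitative core–periphery findings
(higher-tier surfaces less equitable; space metric less equitable than
time; agricultural deprivation at higher tiers) emerge from the assumed
structure — not that any numeric result transfers to a real province.

## Sensitivity analysis

`run_sweep()` varies one parameter at a time from the defaults
(`d0` = 120 min, tertiary weight 2): thresholds 90/120/150 min (30-min
steps) and weights 1.5/2/2.5 (0.5 steps), recomputing the secondary
2SFCA surface and emitting nearest-rank percentile tables plus
(default, variant) scatter pairs. Within a single facility level the
capacity weight is a pure scale factor, so surfaces respond linearly;
with mixed levels per-cell values are still monotone in the weight, and
the population-weighted mean is monotone in `d0`. Both properties are
asserted in the tests.

## Problem sizes and reproducibility

The bundled tests and the acceptance script use the 900-cell default
region (single runs take a couple of seconds), 50–100 random instances
for the conservation/Gini/Moran oracle checks, and 20–50 seeded
replicates for the directional findings. All randomness flows from one
recorded seed; permutation stages use fixed offsets from it so any stage
reproduces in isolation, and `run_all()` writes a manifest with MD5
checksums of every artifact.

## Known limitations

* No turn restrictions, one-way streets, congestion or transit
  schedules; rail has no boarding penalty.
* Collinear-overlap road segments are not merged (the generator never
  emits them); crossing segments are noded.
* The 2SFCA family here is the power-decay variant only — no Gaussian
  kernels, capacity dynamics, or referral-chain simulation.
* LISA p-values are not corrected for multiple testing, matching common
  reporting practice for these maps.
* Dense spatial-weights matrices are fine to a few thousand cells but
  would need sparse storage well beyond that.
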