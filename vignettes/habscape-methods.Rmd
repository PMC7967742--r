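---
title: "Methods: coupled land-use simulation and habitat-quality scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupled land-use simulation and habitat-quality scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

habscape simulates future land use for a multi-scenario planning problem and
scores the habitat quality of the simulated landscapes. The chain has four
stages: (1) a Markov chain projects per-class land demand from an observed
calibration pair of land-use rasters; (2) a single-hidden-layer neural network
learns per-class suitability surfaces from continuous driver rasters; (3) a
cellular automaton allocates the demanded cell counts across the landscape by
local competition among classes; (4) an InVEST-style habitat-quality model
scores each resulting map from distance-decayed threat exposure. This
vignette documents the model, the choices we made where the design was
genuinely open, and what the synthetic test landscapes do and do not
demonstrate.

## Land classes and data model

All stages share one categorical raster vocabulary of eight classes:
cultivated land, garden land, forest, grassland, construction land, water
body, wetland and unused (saline-alkali) land, coded 1-8. Rasters are plain
matrices with `NA` as nodata plus a cell size in meters; nodata cells are
excluded from demand accounting, training, allocation and every statistic.
File exchange uses the ESRI ASCII grid: a text format that carries the grid
shape, the cell size and a nodata sentinel, round-trips integer rasters
bit-faithfully, and keeps 15 significant digits for continuous rasters. We
deliberately support no other raster dialect: this package's R dependencies
include no GDAL bindings, and one lossless, human-readable format keeps every
fixture and output inspectable.

Demands are always integer cell counts internally. Planning areas given in
hectares convert via `cells = area_hm2 * 10000 / cell_size^2`; fractional
results are resolved by largest-remainder rounding, which conserves the
landscape total exactly. The same rounding rule is used for projected Markov
states; we preferred one consistent conservation rule over per-stage ad-hoc
rounding.

## Markov demand

With a transition matrix `P` estimated from the calibration cross-tab (rows
normalized to 1; classes absent at the first date get identity rows), the
projected state is `S_{t+1} = S_t P^n`. The calibration pair spans 8 years
while the projection horizon is 13, so the business-as-usual demand needs
`P^(13/8)`. Fractional powers are taken on the eigen branch; if that yields
entries negative or complex beyond 1e-9 (possible for estimated matrices),
the implementation falls back, with a warning, to linear interpolation
between the enclosing integer powers. Either path is renormalized to
row-stochastic form and the projected counts conserve the cell total. When a
scenario supplies a demand table, that table takes precedence over the Markov
projection; the Markov path is the business-as-usual default only.

## Suitability network

The suitability model is the smallest network matching the stated
architecture: one hidden layer of sigmoid units (default 12, about 0.75 x
the 15 drivers), sigmoid output units, one output per class, trained with a
cross-entropy objective against per-class indicator targets. We use the
`nnet` engine (BFGS optimization, epoch cap 200, fixed seed, hence exactly
reproducible weights). Drivers are min-max normalized to [0, 1] on the
training stack and the bounds are stored in the model; prediction-time
values outside the stored bounds are clamped with a warning. Raw sigmoid
outputs are floored at 1e-12 and divided by their per-cell sum, so the
per-cell class probabilities sum to 1 exactly — the constant-sum constraint
is enforced by construction, not learned. The tiny floor keeps every class
drawable by the allocation roulette without measurably distorting the
probabilities.

Training cells default to a stratified 5% sample (equal counts per class
where possible): the rare classes (garden, grassland, under 1% of the
landscape) would otherwise contribute a handful of samples and the network
would never learn them.

## Cellular-automaton allocation

Each candidate move is scored by the product
`TProb = sp * Omega * Inertia_p * (1 - cost)`, where `sp` is the suitability
probability, `Omega` the neighborhood effect, `Inertia_p` a per-class
self-adjusting coefficient and `cost` is 0 for allowed and 1 for forbidden
conversions, so forbidden transitions score exactly zero.

**Neighborhood effect.** `Omega` is the share of the N x N window (N = 3,
focal cell excluded, denominator fixed at N^2 - 1 = 8) occupied by the
candidate class, times a per-class weight from the scenario tables.
Neighbors outside the raster or in nodata count zero while the denominator
stays 8 — a small, documented suppression of the effect along edges, chosen
over renormalization so that a class fully surrounding a cell always scores
exactly its weight.

**Inertia.** The printed three-case update rule for the inertia coefficient
has overlapping conditions as stated (the "not worsening" case triggers
together with the scaling cases). We resolved it to the evident intent,
keeping exactly the printed ratio factors: keep the coefficient when the
absolute demand gap is not worsening; multiply by `D^(t-2)/D^(t-1)` when
both gaps are negative and worsening (damps an over-allocated class);
multiply by `D^(t-1)/D^(t-2)` when both are positive and worsening (boosts
an under-allocated class). Gaps use `D = demand - allocated`, so positive
means under-allocated. The coefficient is clamped to [1e-3, 1e3] to keep the
score finite under pathological gap sequences.

**Competition.** Each iteration recomputes the neighborhood stack from the
current map, updates the inertia from the last two gaps, then visits the
mutable cells in a seeded random order. A visited cell competes only if its
class currently exceeds its demand; it draws its next class by roulette
wheel over the positive `TProb` of classes whose demand is not yet met
(argmax is available as an option). Every executed move therefore transfers
one cell from a surplus class to a deficit class, which gives two useful
invariants for free: class counts always sum to the mutable-cell total, and
the maximum residual gap is non-increasing across iterations. When the
allowance matrix admits no direct surplus-to-deficit conversion (e.g.
cultivated surplus cannot become garden under the ecological-security
allowances), the automaton opens two-step chains: a surplus cell may then
also move into a class exactly at its demand, which leaves the maximum gap
unchanged and lets a subsequent move complete the transfer. A run stops when
the maximum gap is within `tol` (default 0.1% of the mutable cells), after
`max_iter` (default 300) iterations, or early — flagged unconverged — when a
sweep executes no move even with chains open, or the residual has not
improved for 25 iterations.

Because change can only enter a class where its neighborhood effect is
positive, growth proceeds from existing patches — the intended CA behavior —
and a class absent from the entire landscape can never be seeded. Demands
requiring more cells of a class than are reachable under the allowances fail
fast with a per-class diagnosis rather than looping.

**Restricted areas.** The ecological-redline mask freezes its cells
entirely; the permanent-farmland mask freezes only its cultivated cells,
protecting cultivated land specifically without pinning other classes.
Frozen cells' classes are subtracted from the demand before allocation and
the remainder is rebalanced to the mutable total by largest remainder.

**Validation.** Simulated maps are scored against observations by overall
accuracy (cell-wise agreement) and Cohen's kappa with chance agreement from
the marginal products; kappa is reported as undefined when chance agreement
is 1.

## Habitat quality

Habitat quality per cell is `Q = H_j (1 - D^z / (D^z + k^z))` with habitat
suitability `H_j` per class, scale constant `z = 2.5` and half-saturation
constant `k = 0.5`: quality equals `H_j` where degradation `D` is zero and
loses half its maximum where `D = k`. Construction land has `H = 0` and so
always scores zero. Degradation sums, over six threat types (urban, rural
residential, transportation, mining, cultivated, saline-alkali land) and
over every source cell, the product of the normalized threat weight, the
distance-decayed influence, the accessibility factor and the class's
sensitivity to that threat. Linear influence falls as `1 - d/d_max`;
exponential influence as `exp(-2.99 d / d_max)` and is truncated to zero
beyond `d_max` (about 0.0503 at the cutoff), keeping every kernel finite.
Maximum distances are read in kilometers — the convention of the
ecosystem-services software family this stage follows — and distances are
metric center-to-center distances via the cell size, so results are
invariant to grid resolution for fixed point sources.

The default computation convolves each threat's source raster with its decay
kernel by FFT; a literal brute-force double sum over source cells is kept as
the reference route and the two are required to agree within 1e-6 on every
test fixture. The accessibility raster multiplies degradation exactly as the
formula states (smaller values shelter a cell); since the verbal conventions
around this layer conflict in the literature, the formula is fixed and the
layer is left to the user, defaulting to 1 everywhere.

Two regimes of the index deserve note. Summing influence over *all* source
cells means that a landscape whose threat patches span many cells
accumulates `D` values far above the half-saturation constant, pushing `Q`
toward zero nearly everywhere — on our synthetic delta landscapes (30 m
cells, threats reaching 1-10 km) mean quality is of order 1e-7, and the
published magnitudes for a comparable real landscape are only attainable if
each kernel is normalized to unit mass. `degradation_index(...,
normalize_kernels = TRUE)` provides that variant, turning exposure into a
decay-weighted mean of source presence in [0, 1]. The package default
remains the literal sum, which is what all oracle tests check; the
normalized option changes only the kernel mass, not the structure, so the
same monotonicity and agreement properties hold.

Threat sources are derived from the land-use map. The threat catalogue is
finer than the class list, so an optional subtype raster can resolve
construction into urban/rural/transport/mining and unused land into
saline-alkali/other; without it, a documented default maps construction to
the urban threat, cultivated land to the cultivated threat, unused land to
the saline-alkali threat, and leaves the other three sourceless. The default
is deliberately conservative: simulated future maps carry no subtype
information, and inventing a decomposition would manufacture spatial detail
the simulation does not contain.

Quality maps are graded into five bins — Lower [0, 0.1), Low [0.1, 0.4),
Middle [0.4, 0.6), High [0.6, 0.7), Higher [0.7, 1] — lower-inclusive, with
per-grade area percentages over live cells summing to 100. Scenario
comparison reports per-cell quality change binned at plus/minus 0.1 and 0.4
(configurable) and ranks scenarios by mean quality and by the High + Higher
share.

## Scenarios

Four packaged configurations mirror the printed planning tables: S1
(business as usual: Markov demand, baseline weights, permissive allowances,
no restrictions), S2 (fast cultivated-land expansion: tabled demand,
construction weight 0.9), S3 (ecological security: tabled demand, adjusted
weights, stricter allowances — notably no conversion of any class to unused
land and construction may not become water — and the redline restriction),
and S4 (sustainable development: S3's allowances, its own weights and
demand, redline plus permanent-farmland restrictions). A golden-file test
asserts every number in the packaged demand, weight, allowance, threat and
sensitivity tables against the printed values. Garden land and grassland
hold constant areas in every scenario's demand; we let them participate in
competition rather than freezing them — their constant demand already pins
their totals, and freezing them spatially would be an assumption the tables
do not state.

## Synthetic landscapes

No public rasters exist for the study system, so the generator produces the
full input bundle from a seed: 15 driver layers mirroring the real
categories (3 terrain-like autocorrelated fields, 8 Euclidean-distance
surfaces to random seed points, 2 broad socioeconomic and 2 broad climate
fields); a t0 map whose classes claim their top-scoring cells under fixed
monotone loadings on the drivers (so the suitability stage has a learnable,
known rule); a t1 map obtained by applying a known row-stochastic transition
matrix to the mutable cells, with converting cells chosen
neighborhood-weighted so change arrives in patches rather than
salt-and-pepper; a threat-subtype raster; and redline/farmland masks (smooth
random fields thresholded at the 5% and 20% levels). Class proportions
default to a delta-plain mix (28.5% cultivated, 22.5% water, 15.7%
construction, 15.3% unused, 14.1% wetland, remainder garden/forest/
grassland) and the default transition matrix encodes reclamation of unused
land, urban expansion and water/wetland exchange at rates of 4-14% per
calibration interval.

What passing tests on these landscapes show: exact-arithmetic properties
(normalization, conservation, frozen cells, forbidden transitions,
round-trips) hold unconditionally; statistical recoveries (transition matrix
within 0.02 at 1e5 cells, suitability rule at over 90% held-out agreement,
hindcast kappa well above chance) show the estimators work when the data
actually follow the model. What they do not show: performance on real
landscapes, whose drivers are collinear and shifted between dates, whose
transition process is neither stationary nor cell-independent, and whose
class geometry (roads, rivers) no isotropic random field reproduces.

## Problem sizes and numerical choices

The shipped tests use 80 x 80 landscapes for module contracts, 200 x 200 for
the allocation and normalization properties, 320 x 320 (about 1e5 cells) for
transition recovery, and the 120 x 120 default for end-to-end pipeline runs
— sizes at which every statistical tolerance above has comfortable margin
while the whole suite stays quick on a single core. Other numeric choices:
probabilities floored at 1e-12 before roulette; FFT convolution results
floored at 0 to remove round-off undershoot; transition rows renormalized
after fractional powers; inertia clamped to [1e-3, 1e3]; eigen-branch
tolerance 1e-9; all seeds explicit, with one global seed split
deterministically per stage.

## Known limitations

Demand projection is purely Markovian — no econometric drivers, no
spatially-explicit per-cell chains. The automaton is cell-based; patch-level
or vector change processes are out of scope. The habitat-quality stage
computes no rarity term and no valuation. Scenario outputs inherit the
subtype-mapping conservatism described above: rural, transportation and
mining threats are silent on simulated maps unless the user supplies a
subtype raster.
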