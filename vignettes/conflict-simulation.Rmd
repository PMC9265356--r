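---
title: "Measuring and simulating production-living-ecological space conflict"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and simulating production-living-ecological space conflict}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleconflict)
```

## The problem

Rapid urbanisation pushes construction land into agricultural and
ecological space. Planners describe this competition with the
*production-living-ecological* (PLE) framework: every land-use class is
assigned to one of four space types — living-production (LP, construction
land), production-ecological (PE, agricultural land that also delivers
ecosystem services), ecological-production (EP, woodland and water), and
ecological space (ECO, unused land, mainly other grassland). Conflict
between these spaces is a measurable, mappable quantity, and projecting it
forward under alternative planning scenarios is what this package does:

1. reclassify six-class land-use rasters into PLE space and account areas,
   changes and shares over time;
2. score spatial conflict per square evaluation unit with a composite
   landscape-ecology index;
3. simulate future land use with a Markov demand projection coupled to a
   neural-network-suitability cellular automaton (CA);
4. translate the conflict *transition* between today and the simulated
   future into five functional planning zones.

A synthetic-landscape generator supplies every input, so the whole chain
is reproducible and testable without any external raster product.

## The conflict index

The study region is tiled with 1000 m × 1000 m evaluation units (the
default `unit_size`; boundary units that are only partly covered are kept
and always use the *full* nominal unit area \(A\) in denominators). Within
each unit, patches are maximal connected components of one PLE class,
clipped at the unit boundary; 8-connectivity (queen) is the default, with
4-connectivity available, since landscape-metric software commonly uses
the queen convention. Perimeters count exposed cell edges — edges facing
another class, nodata, or the unit boundary.

Per unit the composite index is

\[ SCCI = SCI + SVI - SRI \]

* **SCI** — spatial complexity, the area-weighted mean patch fractal
  dimension: \( \sum_j \frac{2\ln(0.25\,P_j)}{\ln a_j}\cdot\frac{a_j}{A} \)
  with patch perimeter \(P_j\) (m) and area \(a_j\) (m²). A single square
  patch filling its unit scores exactly 1, which the tests assert to
  1e-12. With cells of at least 1 m the \(\ln a\) singularity cannot
  occur; a 1 m² patch raises an error rather than returning nonsense.
* **SVI** — spatial vulnerability, the area-weighted mean of per-type
  vulnerability scores LP 4, PE 3, EP 2, ECO 1, hence bounded by [0, 4].
  (In some printed formulations the symbol in this sum is mislabelled as a
  perimeter; the score reading is the only one that keeps the index
  dimensionless and bounded, and it is what the accompanying text
  describes.)
* **SRI** — spatial stability, one minus min-max-scaled patch density
  \(PD = n/A\). The most fragmented unit of a date scores 0, the least
  fragmented 1. The printed definition of \(n\) is ambiguous between
  "number of patches" and "number of space types"; patch count is the
  default (`pd_mode = "patches"`) because the space-type reading caps
  \(n\) at 4 and destroys contrast; the variant is kept behind
  `pd_mode = "types"` for sensitivity runs.

Raw SCCI is min-max normalised to [0, 1] and cut into five equal-interval
conflict levels (weaker, weak, medium, strong, stronger). Bins are
half-open with the top bin closed, \([0,0.2)\dots[0.8,1.0]\), so exactly
five levels with no gaps (printed tables show overlapping closed
intervals). When several dates are compared the normalisation pool is
*joint* across dates by default so that levels are commensurable over
time — a time series of level counts only makes sense on a common scale;
`pool = "per_date"` is available because the original choice is not
stated. SRI scaling is always within-date, since fragmentation contrast is
a per-date property.

## The simulation model

**Demand.** A Markov chain calibrated on two dated rasters
(`fit_markov()`) gives the transition matrix \(P_{ab}\); demand is
\(S_{t+1} = P^\top S_t\), one step per calibration interval
(`project_demand()`). A 15-year horizon from a 15-year calibration is one
step — the natural reading when the projection span equals the
calibration span; annualised powers are not used. Demands in km² are
converted to integer cell counts by largest-remainder rounding so totals
conserve exactly.

**Suitability.** A single-hidden-layer feed-forward network (`nnet`,
logistic hidden units, softmax output; 12 hidden nodes by default) is
trained on a uniform sample of cells (default 8% of data cells, within
the usual 5–10% convention), inputs being the standardized driver
rasters. Predictions are renormalised so each cell's class probabilities
sum to 1, an invariant the tests assert everywhere. If a rare class
misses the uniform sample, a stratified redraw guarantees every present
class at least two training cells. The architecture values are declared
defaults, not inferred ones.

**Allocation.** Per iteration and cell, the probability of conversion to
class \(k\) is

\[ TProb_{p,k} = sp_{p,k}\cdot\Omega_{p,k}\cdot Inertia_k\cdot M_{c(p),k} \]

with \(\Omega\) the Moore-neighborhood share of class-\(k\) cells
(window \(N=3\) by default, denominator \(N^2-1\) also at truncated edge
windows) times the class neighborhood weight, and \(M\in\{0,1\}\) the
conversion-allowance matrix used multiplicatively as the \(1-\mathrm{cost}\)
factor (published scenario tables use exactly this 0/1 encoding). The
adaptive inertia multiplier is updated per class from the last two
demand–count gaps \(D\): unchanged when \(D^{(t-2)} \le D^{(t-1)}\),
multiplied by \(D^{(t-2)}/D^{(t-1)}\) when \(0 > D^{(t-2)} > D^{(t-1)}\),
and by \(D^{(t-1)}/D^{(t-2)}\) when \(D^{(t-1)} > D^{(t-2)} > 0\). This is
the rule exactly as printed in the source formulation; its first case
makes the two adjusting branches asymmetric (the overshoot branch *damps*
rather than amplifies), which differs from the absolute-gap convention of
the original FLUS literature. Both are implemented
(`inertia_convention = c("printed", "absolute")`) and neither is asserted
as the original authors' computation.

The allocation discipline itself is not specified in the source
formulation, so the package commits to one and documents it: cells are
visited in descending order of their best achievable `TProb` (ties broken
by a seeded random draw); a cell converts to its best class only while
that class is under demand and its own class over demand; restricted
cells and disallowed transitions never convert. Iteration stops when
every class is within `max(0.5% of demand, 10 cells)` of its target, at
`max_iter = 300`, or when no conversion remains possible — in which case
the unmet residual per class is reported rather than silently absorbed. A
roulette-wheel alternative was considered and rejected for the default
because the deterministic sweep makes runs reproducible cell-for-cell
under a fixed seed.

**Validation.** `kappa_coefficient()` scores simulated against actual
rasters with Cohen's kappa from the cell confusion matrix; the pipeline
reallocates date 1 toward date-2 demand and reports kappa against the
actual date-2 raster.

## Scenarios and their internal tension

`builtin_scenarios()` ships the three planning scenarios — natural
development (ND), cultivated-land protection (CL) and ecological
protection (EP) — with their published allowance matrices, the common
neighborhood weights (0.56, 0.25, 0.36, 0.43, 1, 0.25 for cultivated,
woodland, grassland, water, construction, unused) and the published 2035
demand vectors as a worked configuration. Two properties of those tables
deserve note:

* Under CL the cultivated row still permits conversion (only conversion
  to water is blocked); cultivated protection is expressed through the
  demand vector (smallest cultivated loss) and the basic-farmland
  restriction mask, not through a hard conversion ban.
* In *all three* scenarios no class may convert into water, yet the
  demand vectors project water growth. Demand and allowances are
  therefore mutually infeasible as printed. The CA reports this honestly
  as an unmet residual; the pipeline additionally applies
  `feasible_demand()`, which caps the growth of inflow-blocked classes
  (and the shrinkage of outflow-blocked ones) and redistributes the
  displaced cells by largest-remainder rounding, so scenario runs
  converge while conserving totals.

Scenario demand on synthetic landscapes is derived from the natural
Markov projection by scaling each class's change with the ratio of the
published CL/EP demand changes to the published ND changes
(`scenario_demand_ratios()`), which preserves the scenarios' relative
character at any landscape size.

## Zoning

`transition_codes()` codes each unit's conflict trajectory as
`10 * level(now) + level(future)`. Fifteen codes carry published zone
assignments (ecological protection 11/21/41; ecological conservation
22/32/42; modern agricultural 13/23/33; development coordination
43/34/44; urban optimization 45/54/55). The other ten codes do not occur
in the source study's data, so the rule table is silent about them; the
default fallback assigns them by their end-state level (1–2 conservation,
3 modern agricultural, 4 development coordination, 5 urban optimization),
chosen to preserve the monotone conflict-to-zone gradient of the listed
codes, and flags every fallback unit in the summary.
`fallback = "unassigned"` gives the strict behaviour.

## What the synthetic generator emulates — and what it does not

`synth_config()` defaults describe a flat, plain-type county: 200 × 200
cells of 30 m (6 km × 6 km, so the 1000 m conflict grid has 36 whole
units; non-divisible extents exercise the partial-boundary rule), class
shares 77% cultivated / 1.3% woodland / 0.1% grassland / 9.5% water /
11.6% construction / 0.5% unused, and a per-interval transition matrix
with slow cultivated-to-construction conversion, near-persistent water,
and almost-absorbing construction — the dominant dynamics of such a
county. Drivers (13 layers, mirroring a typical terrain / climate /
socio-economy / accessibility set) are Gaussian-smoothed white noise
(range = smoothing sigma, default 8 cells), odd layers with an extra
monotone gradient, standardized exactly. Class placement rank-thresholds
a per-class linear driver score plus noise, so target shares are hit to
integer rounding and suitability is learnable by construction.
`evolve_landuse()` converts, within each source class, exactly the
largest-remainder share prescribed by the transition row, placing
conversions at the cells most suitable for the target class.

What this does *not* emulate: real hydrology and geomorphology (rivers as
connected linear features), the 25-class secondary legend, registration
error between dates, and demand shocks. Passing tests therefore show that
the method chain is implemented correctly and recovers known structure;
they do not certify accuracy on any real remote-sensing product.

## Numerical choices

* All lengths in meters, areas in m²; areas are reported in km² rounded
  only at report time, while internal accounting is exact cell counts.
* Grassland sits in PE under the default mapping — the placement implied
  by four-type area accounting at the six-class level — while the
  secondary-legend framework puts barren grassland in ECO;
  `ple_mapping("legend")` provides that variant and neither is asserted
  as the original intent.
* Degenerate inputs are defined, not crashed: no fragmentation contrast
  gives SRI 1 everywhere (logged); a degenerate SCCI pool gives all-zero
  normalised values (logged); a zero prior gap freezes a class's inertia;
  an empty scenario list yields a conflict-only pipeline run.
* Change rates from a zero base area are reported as `NA`, not infinity.
* Round-trip agreement of simulated versus held-out class totals is
  asserted at 2% with a two-cell floor: class totals are integers built
  by largest-remainder bookkeeping at both the generator and demand
  steps, so sub-cell percentage bands are below the resolution of the
  quantity itself (2% of the 0.1%-share grassland class is less than one
  cell on the default grid).

## Problem sizes

The test suite and the acceptance script run the default 200 × 200
pipeline (about 5 s end to end), a 500 × 500 pair for Markov parameter
recovery, and 50 × 50 random rasters for the brute-force oracle
equivalence checks — sizes chosen so the full chain, including three
scenario simulations, remains interactive on a single CPU while every
boundary rule (partial units, truncated windows, rare classes) is still
exercised.

## A short tour

```{r, eval = FALSE}
library(pleconflict)

res <- run_pipeline(pipeline_config(seed = 1))
res

# areas, changes, shares
res$areas_ple
area_changes(res$areas_landuse)

# conflict now and in 2035 under each scenario
summarize_conflict(res$conflict_now)
autoplot(res$conflict_now)

# calibrated model
tidy(res$markov)
glance(res$suitability)

# zones
res$zoning$summary
plot_zones(res$zoning)
```

## Known limitations

* The CA converts a cell only to its single best class per pass; when
  that class fills mid-pass the cell waits for the next iteration. This
  costs iterations, never correctness.
* Water demand growth is structurally infeasible under all three
  published allowance matrices (see above); results under
  `feasible_demand()` are conditional on that adjustment.
* The conflict grid assigns straddling cells by their upper-left corner;
  with cell sizes that do not divide the unit size, unit areas can differ
  from the nominal area by up to one cell row/column — consistent with
  the full-nominal-area convention for partial units.
* Suitability accuracy depends on the generator's signal-to-noise
  (`noise_sd`); heavily noised landscapes will lower kappa without
  indicating an implementation fault.
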