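---
title: "The pasture-livestock model: equations, engine and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The pasture-livestock model: equations, engine and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palsim)
```

`palsim` simulates the daily dynamics of grazed pastureland — vegetation
growth under climatic and nutrient limitation, livestock intake, digestion,
weight change and excretion, and the soil nitrogen cycle — on a raster grid.
Its defining feature is *how* the pieces are wired together: every quantity
is a named concept, every computation is a self-contained component model
producing exactly one concept from other concepts, and a query is answered by
resolving, at run time, the directed acyclic graph of components that leads
to the requested concept. This vignette documents the model equations, the
engine semantics and the choices made where the design was genuinely open.

## The model

### Climatic limiting factors

Vegetation growth is throttled by dimensionless factors in $[0,1]$, one per
abiotic constraint, combined multiplicatively:

* **Temperature** ($FT$): a trapezoid over the daily mean temperature with
  cardinal points $T_{base} < T_{opt,lo} \le T_{opt,hi} < T_{max}$ — zero
  outside $(T_{base}, T_{max})$, one on the optimal plateau, linear ramps
  between. The trapezoid is the standard minimal form with the right
  monotonicity and endpoints; all four cardinal temperatures live in the
  vegetation parameter table so other response shapes can be emulated by
  recalibration.
* **Radiation** ($FR$): a saturating Michaelis–Menten response
  $FR = r_{g2} / (r_{g2} + r_{half})$ to the radiation actually reaching the
  vegetation. $FR$ attains 1 only in the saturating limit; over any finite
  sweep it stays strictly below 1.
* **Understory radiation** ($r_{g2}$): where a cell carries an overstory
  (its overstory code `com2` differs from the main code `com`), only a fixed
  fraction — 0.2 by default — of the incident radiation penetrates the
  canopy; otherwise the full radiation passes. The rule is homogeneous of
  degree 1 in the radiation, which the tests exploit.
* **Moisture** ($FH$): a single-bucket plant-available water balance per
  cell. The bucket holds `whc` mm; the factor is the capped fill ratio
  $FH = \min(1, (W/whc)/w_{crit})$. Each day, actual evapotranspiration is
  potential evapotranspiration scaled by $FH$ (evaluated on the pre-step
  state) and capped at the available water; storage above `whc` drains. The
  balance closes exactly: precipitation equals storage change plus actual
  evapotranspiration plus drainage, every cell, every day. Potential
  evapotranspiration is estimated from radiation and temperature in an
  Oudin-style form, $PET = \frac{R_g}{2.45}\,\frac{\max(0, T+5)}{100}$
  mm day⁻¹ — a deliberate one-line surrogate: the bucket needs a demand
  term, not a full Penman–Monteith stack.
* **Phenology** ($ph$): a per-type day-of-year activity calendar in
  $[0,1]$, by default a trapezoid over the growing season (full activity
  between `season_start` and `season_end`, linear ramps of `ramp_days`).

The combined abiotic factor is the product $FTRH = FT \times FR \times FH$.
A product rather than a minimum was chosen because it is symmetric, smooth
and strictly monotone in each argument while still bounded by the most
limiting factor; whether the original empirical formulation composed its
factors this way is not recoverable from available documentation, so the
composition is flagged as a calibration point.

### Vegetation life cycle

Potential daily growth is exactly

$$\text{potential} = x_f \cdot FTRH \cdot ph \qquad [\mathrm{g\,m^{-2}\,day^{-1}}]$$

with $x_f$ the vegetation type's maximum daily growth. Actual growth scales
potential by the **nitrogen factor** $FN$ (below); livestock influence
growth only through biomass removal, never as a growth-rate modifier — the
minimal mechanism that the ingestion pathway already requires.

Three biomass pools are tracked per cell: living above-ground biomass,
standing dead, and litter. Senescence moves living mass to standing dead at
a first-order rate modulated by $(1 - ph)$, so it peaks when the canopy is
dormant; litterfall moves standing dead to litter at a first-order rate;
litter decomposes at the mineralization rate. Harvest events remove a
fraction of the living pool on their dates.

Whenever the outflows demanded from a pool in one day exceed the pool plus
its same-day inflow, *all* outflows from that pool are rescaled by a common
factor so the pool lands exactly at zero and the daily mass balance still
closes. The engine expresses these rescales as explicit `*_outflow_scale`
components, so the realized (post-rescale) fluxes are themselves queryable
concepts and the budget can be audited from the store alone.

### Livestock

Each livestock group (cattle or mares) has a density raster (animals per
cell), fixed within a run — no daily movement model is attempted. Grazing
demand per cell is density × maximum intake × terrain accessibility.
Accessibility declines linearly with slope between two thresholds; the
cattle thresholds (10–30°) sit strictly inside the mares' (15–40°), so
cattle accessibility never exceeds mare accessibility — the species ordering
the system is built to respect. When total demand exceeds the palatable
supply (a palatability fraction of the living plus standing dead pools),
supply is shared proportionally to demand — competition is species-blind
proportional rationing, which is order-independent and gives every group the
same satisfaction. Living biomass is consumed preferentially over dead.

Digestion splits intake by a digestibility fraction; weight change is a
linear energy-balance surrogate on digestible dry matter,

$$\Delta w = \epsilon\,(I_{dig} - m\,w),$$

with conversion efficiency $\epsilon$ (kg g⁻¹) and maintenance coefficient
$m$ (g kg⁻¹ day⁻¹). Weight falls when intake misses maintenance and
converges monotonically to $I_{dig}/m$ under constant intake. No
metabolizable-energy ladder is modelled: the linear surrogate preserves
every qualitative behaviour the system needs (negative change possible,
sensitivity to topography and availability) with two interpretable
parameters.

Ingested nitrogen not retained by the animal returns to the system split
between solid manure (to the litter organic pool) and urine (directly to
soil mineral nitrogen): retained + solid + urine equals ingested N exactly.

### Nitrogen cycle

Pools per cell: soil mineral N, litter organic N, N in living biomass, N in
standing dead, plus a small *reabsorption credit* pool. Fluxes:

* **Mineralization**: first-order on litter organic N, modulated by
  $FT \times FH$ — frozen or dry soil mineralizes nothing.
* **Uptake and $FN$**: demand is potential growth × the type's target
  tissue N concentration, net of the reabsorption credit; soil uptake covers
  what the credit cannot, capped at the mineral pool. $FN$ is the fraction
  of demand met, and 1 when demand is zero.
* **Reabsorption**: a fraction of the N in senescing tissue is withdrawn
  into the credit pool and deducted from *next-step* demand (same-step
  buffering would create a cycle between uptake and senescence within the
  day; next-step is the cheapest acyclic reading and is documented as such).
* **Leaching**: drainage-proportional,
  $\text{flux} = N_{min} \cdot \min(1, \text{drainage}/whc)$ — zero without
  drainage; a full bucket volume of drainage flushes the pool.

The uptake-and-leaching pair is jointly rescaled against the mineral pool.
That rescale deliberately ignores the same-day inflows (mineralization,
urine, fertilization): counting them would route a dependency from excretion
back into uptake and create a cycle. Ignoring inflows is conservative — the
pool can only end higher than the guard assumes — and keeps the within-day
graph acyclic.

The whole-system budget closes each step:
$\Delta(\sum \text{pools}) + \text{retained} = \text{fertilization} - \text{leaching}$,
which the test suite verifies to below $10^{-9}$ g N m⁻² per day over full
annual runs.

## The dataflow engine

Components declare inputs purely as concept ids. `resolve()` walks the
dependency closure of a query: candidate producers are ranked by scoping
(same namespace > same project > global) with lexicographic id as the
deterministic tie-break, and the result is a DAG whose sinks are the queried
concepts. On a timeline longer than one step, any resolved concept with a
registered *change model* becomes a state variable: the change model and its
own dependencies are inserted automatically, and the state advances by
explicit Euler with a one-day step, $X(t{+}1) = X(t) + \Delta X(t)$. On a
single-step timeline the change model is not inserted and the concept stays
static — adding a change model is all it takes to dynamize a concept.

Within a step, a state concept's value is known at step start, so consumers
of states impose no ordering constraints; all other dependencies order the
components topologically (Kahn's algorithm, sorted ready set, so resolution
and execution order are reproducible). Reads of concepts never written are
hard errors, as are non-finite outputs (reported with component and cell) —
missing initialization should surface, not default to zero.

One intra-day operation order had to be fixed, since only the between-theme
dependencies are structural: climate factors → phenology → potential growth
→ nitrogen supply and $FN$ → actual growth → ingestion → digestion and mass
change → excretion → senescence → litterfall → pool updates. This order
makes grazing act on current-day biomass and keeps both budgets closed; it
is encoded purely in the concept dependencies, not in any scheduler. A
consequence, verified by test: executing any component standalone on the
fields stored by a full run reproduces the full run's output for that
component bit-for-bit, and the whole modular run matches an independently
written monolithic loop to floating-point accuracy on a 5×5 grid over 30
days.

External inputs are mediated on the fly: a field on a different grid is
resampled to the context grid (area-weighted mean for continuous fields,
nearest neighbour for categorical, nodata where source coverage is below
half a cell), and a value in a different unit of the same dimension is
converted to the concept's unit. A single planar reference is assumed;
reprojection is out of scope. Coarser-than-daily series are expanded by
step-function repetition.

Each run can emit its provenance: the resolved dataflow as a DOT digraph
(per-node provenance tagged resource / table / expression) and a Markdown
report structured as introduction, methods (every executed component with
its provenance), results (summary statistics per queried concept),
discussion, conclusion and references.

## The synthetic landscape

The generator produces every input the model needs, deterministically from
one seed, with each artifact drawn from its own named substream so
regenerating one artifact never perturbs another. It emulates a temperate
Atlantic mountain pastureland: elevations spanning 100–1200 m (smooth
correlated surface; slope by central differences), a mosaic of nine
vegetation types in contiguous Voronoi patches with an optional overstory
code, daily climate with a 14 °C annual mean temperature (sinusoidal
seasonal cycles with seeded noise; precipitation rescaled to its configured
mean; radiation floored at 0.1 MJ m⁻² day⁻¹), and 14 livestock groups of
cattle and mares placed on low-slope cells, never where slope exceeds the
species' accessibility cutoff.

What the generator does *not* emulate: real spatial covariance of climate
with elevation (climate is spatially uniform per day), observed vegetation
maps, realistic herd management, or measured parameter values — the
parameter tables are desk defaults chosen for plausible magnitudes (maximum
growth rates up to ≈5.5 g m⁻² day⁻¹, tissue N around 2–3%, cattle ≈550 kg).
Passing tests therefore demonstrate the *mechanics* — bounds, budgets,
modularity, determinism — not predictive skill on any real landscape, which
would require site calibration data this package does not ship.

## Numerical choices and problem sizes

* Explicit Euler at Δt = 1 day, matching the daily timestep of the model;
  no stiffness arises at the parameter magnitudes used.
* Pool non-negativity via common proportional rescaling of outflows
  (exact), with a `pmax(0, ·)` guard absorbing only float rounding.
* Unit round-trips are exact to 1e−12 relative; budget closure is tested at
  1e−9 absolute per day against pools of order 10²; engine-vs-oracle
  equivalence at 1e−9 per cell per step.
* Test problem sizes: 5×5 × 30 days for the oracle comparison, 40×40 × 365
  days for the conservation suites, chosen as the smallest sizes that
  exercise every pathway (competition, rescaling, drainage, dormancy) while
  keeping the default suite quick on a laptop.
* The default context (50 m cells, daily steps, 2018–2050, 12053 steps) is
  the configuration a full-scale study would use; tests and examples run on
  shorter timelines of the same machinery.

## Tabular and graphical surfaces

The core objects (fields, registries, dataflows, stores) are lightweight S3
structures because they are not data frames at heart; everything tabular
enters and leaves as a tibble (`zonal_statistics()`, climate series,
parameter tables, `tidy()` on stores and dataflows, `glance()` for one-row
summaries), and `autoplot()` / `plot_timeseries()` give ggplot2 views of
fields and trajectories.

## Known limitations

* No reprojection, vector geometries or sub-daily steps.
* Spatially uniform daily climate (per-cell exposure scales radiation; a
  lapse-rate model would be the natural next step).
* Livestock are stationary within a run; no demography, milk or economics.
* No gaseous N losses, deposition or fixation (a constant fertilization
  input can stand in for chronic deposition).
* The overstory affects only radiation; any other overstory effects are not
  modelled.
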