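# palsim — modular pasture and livestock simulation

`palsim` is an R toolkit for simulating grazed pastureland at a daily
timestep on a raster grid: vegetation growth under climatic and nutrient
limitation, the vegetation life cycle (senescence, litterfall, harvest),
livestock grazing (intake with competition, digestion, weight change,
excretion) and the soil nitrogen cycle (mineralization, plant uptake and
reabsorption, leaching). It is written for pasture and rangeland modellers
who want each piece of such a system to be independently runnable and
auditable rather than buried in one monolithic loop.

## The model in brief

Daily potential growth of above-ground biomass is

    potential = xf · FTRH · ph        [g m⁻² day⁻¹]

where `xf` is the vegetation type's maximum daily growth, `ph` the
phenological activity for the day of year, and `FTRH = FT·FR·FH` the product
of the temperature, radiation and moisture limiting factors, each in [0, 1]
(trapezoidal temperature response; saturating light response on the
radiation reaching the vegetation — a fixed fraction 0.2 under an overstory;
capped fill-ratio response of a single soil-water bucket). Actual growth is
potential growth times the nitrogen factor `FN`, the fraction of the
nitrogen demand of growth that soil mineral N plus reabsorbed N can supply.
Livestock demand forage in proportion to density, maximum intake and a
slope-dependent accessibility (cattle more terrain-limited than mares);
short supply is rationed proportionally, weight change is conversion
efficiency times the surplus of digestible intake over maintenance, and
excreted N returns to the litter and mineral pools. All pool updates close
their mass and nitrogen budgets exactly, with outflows proportionally
rescaled when a pool would go negative.

The distinctive part is the **dataflow engine**: every quantity is a named
concept, every computation a component model producing one concept from
others, organised in ten thematic namespaces (moisture, radiation,
temperature, vegetation growth, senescence, litterfall, ingestion, livestock
mass, excretion, nitrogen). A query such as `"nitrogen.leaching"` is
resolved at run time into a DAG of components, executed over a user-chosen
grid and timeline, with units and grids of inputs mediated on the fly.
Registering a *change model* for a concept automatically makes that concept
a dynamic state variable on multi-step timelines (explicit Euler, Δt = 1
day). Every run can export its provenance: a DOT dataflow graph and a
structured Markdown report.

A seeded synthetic-landscape generator (terrain, vegetation mosaic with
overstory, daily climate with 14 °C annual mean, cattle and mare herds on
accessible terrain) provides all inputs, so everything here runs without any
external data.

## Worked example

```r
library(palsim)

# a reproducible 20x20 synthetic landscape with 6 livestock groups
ls <- generate_landscape(
  landscape_config(seed = 1, ncols = 20, nrows = 20, n_livestock_groups = 6),
  n_days = 365
)

run <- pal_run(ls, query = c("vegetation_growth.potential_growth",
                             "vegetation_growth.actual_growth",
                             "nitrogen.leaching"))
run$dataflow
#> <dataflow> query ...: 63 components, 23 external inputs, 8 state concepts

# spatial field on 1 June (step 152)
get_field(run$store, "vegetation_growth.potential_growth", 152)
#> <field> vegetation_growth.potential_growth [g/m2/day, continuous] on
#> 20 x 20 grid; min 0.9428 / mean 2.968 / max 4.082

# May summary of the growth concepts
df  <- tidy(run$store, c("vegetation_growth.potential_growth",
                         "vegetation_growth.actual_growth"))
may <- df[format(df$date, "%m") == "05", ]
mean(may$mean[may$concept == "vegetation_growth.potential_growth"])
#> [1] 2.928
mean(may$mean[may$concept == "vegetation_growth.actual_growth"])
#> [1] 0.655
```

Potential growth in late spring averages about 2.9 g m⁻² day⁻¹ over this
landscape (peaking at 4.3), while actual growth averages about 0.65 — the
gap is the nitrogen limitation, the most uniformly binding factor under the
default parameterisation. `plot_timeseries(run$store, "nitrogen.leaching")`
shows leaching pulses riding on drainage events, and
`autoplot(get_field(run$store, "vegetation_growth.actual_growth"))` maps the
final-step field. `export_dataflow(run$dataflow)` and
`generate_report(run$store)` produce the provenance artefacts.

A command-line wrapper for batch use lives at `inst/cli/pal.R`
(`list-concepts`, `query --config run.yaml`, `generate-fixtures`).

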