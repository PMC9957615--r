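#' Default parameter tables
#'
#' Per-vegetation-type parameters for the climate responses, growth,
#' senescence, litterfall and nitrogen cycling, and per-group livestock
#' parameters. Values are desk defaults for a temperate Atlantic pastureland
#' setting: nine vegetation types spanning productive grassland to shrubland,
#' cattle and mare groups with cattle more constrained by terrain.
#'
#' @param n Number of vegetation types (default 9).
#' @return A tibble, one row per vegetation code.
#' @export
default_vegetation_params <- function(n = 9) {
  code <- seq_len(n)
  # productive grasslands (low codes) to sparse shrubland (high codes)
  prod <- seq(1, 0.4, length.out = n)
  tibble::tibble(
    code = code,
    name = paste0("pasture_type_", code),
    xf = round(2 + 3.5 * prod, 2),              # g/m2/day, max ~5.5
    t_base = round(seq(2, 4, length.out = n), 1),
    t_opt_lo = round(seq(12, 15, length.out = n), 1),
    t_opt_hi = round(seq(20, 23, length.out = n), 1),
    t_max = round(seq(35, 38, length.out = n), 1),
    rg_half = round(seq(6, 9, length.out = n), 1),   # MJ/m2/day
    w_crit = round(seq(0.5, 0.65, length.out = n), 2),
    whc = round(seq(140, 80, length.out = n)),       # mm
    senescence_rate = round(seq(0.010, 0.025, length.out = n), 4),
    litterfall_rate = round(seq(0.015, 0.035, length.out = n), 4),
    k_min = round(seq(0.004, 0.008, length.out = n), 4),
    reabs_fraction = round(seq(0.5, 0.35, length.out = n), 2),
    n_conc_target = round(seq(0.030, 0.018, length.out = n), 4), # g N / g
    digestibility = round(seq(0.70, 0.45, length.out = n), 2),
    palatability = round(seq(0.70, 0.35, length.out = n), 2),
    season_start = round(seq(70, 95, length.out = n)),
    season_end = round(seq(300, 280, length.out = n)),
    ramp_days = rep(25, n)
  )
}

#' @rdname default_vegetation_params
#' @param n_groups Number of livestock groups (default 14, alternating
#'   cattle and mares).
#' @param herd_size Animals per group.
#' @export
default_livestock_params <- function(n_groups = 14, herd_size = 20) {
  species <- rep(c("cattle", "mare"), length.out = n_groups)
  idx <- stats::ave(seq_len(n_groups), species, FUN = seq_along)
  tibble::tibble(
    group_id = sprintf("%s_%02d", species, idx),
    species = species,
    herd_size = herd_size,
    mean_weight = ifelse(species == "cattle", 550, 450),        # kg
    intake_max = ifelse(species == "cattle", 12000, 10000),     # g/animal/day
    maintenance_coeff = ifelse(species == "cattle", 10, 9),     # g/kg/day
    conversion_eff = 1e-3,                                      # kg per g
    n_retention = ifelse(species == "cattle", 0.15, 0.12),
    solid_fraction = ifelse(species == "cattle", 0.6, 0.55)
  )
}

# per-cell parameter lookup by vegetation code
.lookup <- function(com, veg_params, column) {
  v <- veg_params[[column]][match(as.vector(com), veg_params$code)]
  matrix(v, nrow(com), ncol(com))
}

#' Build the default PaL model registry
#'
#' Registers the full set of component models across the ten thematic
#' namespaces — moisture, radiation, temperature, vegetation growth,
#' senescence, litterfall, ingestion, livestock mass, excretion and nitrogen —
#' plus change models for every state concept (soil water, the three biomass
#' pools, the nitrogen pools, per-group livestock weight), and declares the
#' external input concepts. Parameter tables are closed over by the compute
#' functions; all per-step arithmetic is delegated to the exported science
#' primitives, so a component executed standalone is the same code as inside
#' a full dataflow.
#'
#' @param veg_params Vegetation parameter tibble
#'   (see [default_vegetation_params()]).
#' @param livestock_params Livestock parameter tibble
#'   (see [default_livestock_params()]); use `NULL` or a zero-row tibble for
#'   an ungrazed system.
#' @param understory_factor Fraction of radiation penetrating an overstory.
#' @return A `pal_registry`.
#' @export
pal_default_registry <- function(veg_params = default_vegetation_params(),
                                 livestock_params = default_livestock_params(),
                                 understory_factor = 0.2) {
  if (is.null(livestock_params)) livestock_params <- default_livestock_params(0)
  vp <- veg_params
  lp <- livestock_params
  calendars <- lapply(seq_len(nrow(vp)), function(i) {
    phenology_calendar(vp$season_start[i], vp$season_end[i], vp$ramp_days[i])
  })
  names(calendars) <- as.character(vp$code)
  calendar_matrix <- do.call(rbind, calendars)  # type x doy lookup

  r <- model_registry()

  ## ---- concepts (units drive mediation and reporting) ----
  cu <- list(
    "climate.tmean" = c("degC", "daily mean air temperature"),
    "climate.precip" = c("mm/day", "precipitation"),
    "climate.rg" = c("MJ/m2/day", "incident solar radiation"),
    "terrain.slope" = c("degree", "terrain slope"),
    "terrain.exposure" = c("1", "topographic radiation exposure multiplier"),
    "vegetation.type" = c("code", "main vegetation code (com)"),
    "vegetation.overstory_type" = c("code", "overstory vegetation code (com2)"),
    "vegetation.harvest_fraction" = c("1", "harvested fraction of living biomass"),
    "nitrogen.fertilization" = c("gN/m2/day", "mineral N fertilization"),
    "moisture.soil_water" = c("mm", "plant-available soil water"),
    "vegetation.living_biomass" = c("g/m2", "living above-ground biomass"),
    "vegetation.standing_dead_biomass" = c("g/m2", "standing dead biomass"),
    "vegetation.litter_biomass" = c("g/m2", "litter biomass"),
    "nitrogen.soil_mineral_n" = c("gN/m2", "soil mineral nitrogen"),
    "nitrogen.litter_organic_n" = c("gN/m2", "litter organic nitrogen"),
    "nitrogen.living_n" = c("gN/m2", "nitrogen in living biomass"),
    "nitrogen.standing_dead_n" = c("gN/m2", "nitrogen in standing dead biomass"),
    "nitrogen.reabsorption_credit" = c("gN/m2", "reabsorbed N credited to uptake"),
    "temperature.limiting_factor" = c("1", "temperature limiting factor FT"),
    "radiation.limiting_factor" = c("1", "radiation limiting factor FR"),
    "moisture.limiting_factor" = c("1", "moisture limiting factor FH"),
    "nitrogen.limiting_factor" = c("1", "nitrogen limiting factor FN"),
    "radiation.over_vegetation" = c("MJ/m2/day", "solar radiation over vegetation (rg2)"),
    "vegetation_growth.combined_limiting_factor" = c("1", "combined abiotic factor FTRH"),
    "vegetation_growth.phenology_activity" = c("1", "phenology activity ph"),
    "vegetation_growth.potential_growth" = c("g/m2/day", "potential growth"),
    "vegetation_growth.actual_growth" = c("g/m2/day", "actual growth"),
    "moisture.drainage" = c("mm/day", "soil water drainage"),
    "nitrogen.leaching" = c("gN/m2/day", "nitrogen leaching"),
    "ingestion.intake_total" = c("g/m2/day", "total grazed biomass"),
    "ingestion.satisfaction" = c("1", "fraction of grazing demand met")
  )
  for (id in names(cu)) {
    r <- register_concept(r, concept(id, description = cu[[id]][2], units = cu[[id]][1]))
  }

  ## ---- external inputs ----
  externals <- c(
    "climate.tmean", "climate.precip", "climate.rg",
    "terrain.slope", "terrain.exposure",
    "vegetation.type", "vegetation.overstory_type",
    "vegetation.harvest_fraction", "nitrogen.fertilization",
    "moisture.soil_water",
    "vegetation.living_biomass", "vegetation.standing_dead_biomass",
    "vegetation.litter_biomass",
    "nitrogen.soil_mineral_n", "nitrogen.litter_organic_n",
    "nitrogen.living_n", "nitrogen.standing_dead_n",
    "nitrogen.reabsorption_credit"
  )
  for (e in externals) r <- declare_external(r, e)

  add <- function(reg, id, ns, output, inputs, compute, ...) {
    register_component(reg, component_model(
      id = id, namespace = ns, output = output, inputs = inputs,
      compute = compute, ...
    ))
  }

  ## ---- temperature ----
  r <- add(r, "temperature.limiting_factor", "temperature",
           "temperature.limiting_factor",
           c("climate.tmean", "vegetation.type"),
           function(ins, t, ctx) {
             com <- ins[["vegetation.type"]]
             temperature_factor(
               ins[["climate.tmean"]],
               .lookup(com, vp, "t_base"), .lookup(com, vp, "t_opt_lo"),
               .lookup(com, vp, "t_opt_hi"), .lookup(com, vp, "t_max")
             )
           }, provenance = "table",
           description = "trapezoidal temperature response (FT)")

  ## ---- radiation ----
  r <- add(r, "radiation.at_surface", "radiation", "radiation.at_surface",
           c("climate.rg", "terrain.exposure"),
           function(ins, t, ctx) ins[["climate.rg"]] * ins[["terrain.exposure"]],
           description = "incident radiation scaled by topographic exposure")
  r <- add(r, "radiation.over_vegetation", "radiation",
           "radiation.over_vegetation",
           c("radiation.at_surface", "vegetation.type", "vegetation.overstory_type"),
           function(ins, t, ctx) {
             radiation_over_vegetation(
               ins[["radiation.at_surface"]], ins[["vegetation.type"]],
               ins[["vegetation.overstory_type"]], understory_factor
             )
           },
           description = "understory conditional: full rg without overstory, a fixed fraction under one")
  r <- add(r, "radiation.limiting_factor", "radiation",
           "radiation.limiting_factor",
           c("radiation.over_vegetation", "vegetation.type"),
           function(ins, t, ctx) {
             radiation_factor(ins[["radiation.over_vegetation"]],
                              .lookup(ins[["vegetation.type"]], vp, "rg_half"))
           }, provenance = "table",
           description = "saturating light response (FR)")

  ## ---- moisture ----
  r <- add(r, "moisture.potential_evapotranspiration", "moisture",
           "moisture.potential_evapotranspiration",
           c("climate.rg", "climate.tmean"),
           function(ins, t, ctx) {
             potential_evapotranspiration(ins[["climate.rg"]], ins[["climate.tmean"]])
           }, description = "radiation-temperature PET estimate")
  r <- add(r, "moisture.limiting_factor", "moisture", "moisture.limiting_factor",
           c("moisture.soil_water", "vegetation.type"),
           function(ins, t, ctx) {
             com <- ins[["vegetation.type"]]
             moisture_factor(ins[["moisture.soil_water"]],
                             .lookup(com, vp, "whc"), .lookup(com, vp, "w_crit"))
           }, provenance = "table",
           description = "bucket fill ratio response (FH)")
  r <- add(r, "moisture.actual_evapotranspiration", "moisture",
           "moisture.actual_evapotranspiration",
           c("moisture.potential_evapotranspiration", "moisture.limiting_factor",
             "moisture.soil_water", "climate.precip"),
           function(ins, t, ctx) {
             pmin(ins[["moisture.potential_evapotranspiration"]] *
                    ins[["moisture.limiting_factor"]],
                  ins[["moisture.soil_water"]] + ins[["climate.precip"]])
           }, description = "PET scaled by FH, capped at available water")
  r <- add(r, "moisture.drainage", "moisture", "moisture.drainage",
           c("moisture.soil_water", "climate.precip",
             "moisture.actual_evapotranspiration", "vegetation.type"),
           function(ins, t, ctx) {
             pmax(0, ins[["moisture.soil_water"]] + ins[["climate.precip"]] -
                    ins[["moisture.actual_evapotranspiration"]] -
                    .lookup(ins[["vegetation.type"]], vp, "whc"))
           }, description = "bucket overflow")
  r <- add(r, "moisture.change_in_soil_water", "moisture",
           "moisture.change_in_soil_water",
           c("climate.precip", "moisture.actual_evapotranspiration",
             "moisture.drainage"),
           function(ins, t, ctx) {
             ins[["climate.precip"]] - ins[["moisture.actual_evapotranspiration"]] -
               ins[["moisture.drainage"]]
           },
           is_change_model = TRUE, of_concept = "moisture.soil_water",
           description = "daily water balance of the bucket")

  ## ---- vegetation growth ----
  r <- add(r, "vegetation_growth.phenology_activity", "vegetation_growth",
           "vegetation_growth.phenology_activity", c("vegetation.type"),
           function(ins, t, ctx) {
             doy <- as.integer(strftime(timeline_dates(ctx$timeline)[t], "%j"))
             com <- ins[["vegetation.type"]]
             idx <- match(as.vector(com), vp$code)
             v <- calendar_matrix[cbind(idx, doy)]
             matrix(v, nrow(com), ncol(com))
           }, provenance = "table", time_dependent = TRUE,
           description = "day-of-year activity from the phenology calendar (ph)")
  r <- add(r, "vegetation_growth.combined_limiting_factor", "vegetation_growth",
           "vegetation_growth.combined_limiting_factor",
           c("temperature.limiting_factor", "radiation.limiting_factor",
             "moisture.limiting_factor"),
           function(ins, t, ctx) {
             combine_limiting(ins[["temperature.limiting_factor"]],
                              ins[["radiation.limiting_factor"]],
                              ins[["moisture.limiting_factor"]])
           }, description = "FTRH = FT * FR * FH")
  r <- add(r, "vegetation_growth.potential_growth", "vegetation_growth",
           "vegetation_growth.potential_growth",
           c("vegetation_growth.combined_limiting_factor",
             "vegetation_growth.phenology_activity", "vegetation.type"),
           function(ins, t, ctx) {
             potential_growth(.lookup(ins[["vegetation.type"]], vp, "xf"),
                              ins[["vegetation_growth.combined_limiting_factor"]],
                              ins[["vegetation_growth.phenology_activity"]])
           }, description = "xf * ftrh * ph")
  r <- add(r, "vegetation_growth.actual_growth", "vegetation_growth",
           "vegetation_growth.actual_growth",
           c("vegetation_growth.potential_growth", "nitrogen.limiting_factor"),
           function(ins, t, ctx) {
             actual_growth(ins[["vegetation_growth.potential_growth"]],
                           ins[["nitrogen.limiting_factor"]])
           }, description = "potential growth under nitrogen limitation")
  r <- add(r, "vegetation_growth.raw_harvest", "vegetation_growth",
           "vegetation_growth.raw_harvest",
           c("vegetation.living_biomass", "vegetation.harvest_fraction"),
           function(ins, t, ctx) {
             ins[["vegetation.living_biomass"]] * ins[["vegetation.harvest_fraction"]]
           }, description = "harvest demand before pool limitation")
  r <- add(r, "vegetation_growth.living_outflow_scale", "vegetation_growth",
           "vegetation_growth.living_outflow_scale",
           c("vegetation.living_biomass", "vegetation_growth.actual_growth",
             "senescence.raw_flux", "vegetation_growth.raw_harvest",
             "ingestion.raw_intake_living"),
           function(ins, t, ctx) {
             outflow_scale(
               ins[["vegetation.living_biomass"]],
               ins[["vegetation_growth.actual_growth"]],
               ins[["senescence.raw_flux"]] + ins[["vegetation_growth.raw_harvest"]] +
                 ins[["ingestion.raw_intake_living"]]
             )
           }, description = "common rescale keeping the living pool non-negative")
  r <- add(r, "vegetation_growth.harvest", "vegetation_growth",
           "vegetation_growth.harvest",
           c("vegetation_growth.raw_harvest", "vegetation_growth.living_outflow_scale"),
           function(ins, t, ctx) {
             ins[["vegetation_growth.raw_harvest"]] *
               ins[["vegetation_growth.living_outflow_scale"]]
           }, description = "realized harvest flux")
  r <- add(r, "vegetation_growth.change_in_living_biomass", "vegetation_growth",
           "vegetation_growth.change_in_living_biomass",
           c("vegetation_growth.actual_growth", "senescence.flux",
             "vegetation_growth.harvest", "ingestion.intake_living"),
           function(ins, t, ctx) {
             ins[["vegetation_growth.actual_growth"]] - ins[["senescence.flux"]] -
               ins[["vegetation_growth.harvest"]] - ins[["ingestion.intake_living"]]
           },
           is_change_model = TRUE, of_concept = "vegetation.living_biomass",
           description = "daily balance of living biomass")

  ## ---- senescence ----
  r <- add(r, "senescence.raw_flux", "senescence", "senescence.raw_flux",
           c("vegetation.living_biomass", "vegetation_growth.phenology_activity",
             "vegetation.type"),
           function(ins, t, ctx) {
             senescence_flux(ins[["vegetation.living_biomass"]],
                             .lookup(ins[["vegetation.type"]], vp, "senescence_rate"),
                             ins[["vegetation_growth.phenology_activity"]])
           }, provenance = "table",
           description = "first-order senescence, peaking at low phenological activity")
  r <- add(r, "senescence.flux", "senescence", "senescence.flux",
           c("senescence.raw_flux", "vegetation_growth.living_outflow_scale"),
           function(ins, t, ctx) {
             ins[["senescence.raw_flux"]] * ins[["vegetation_growth.living_outflow_scale"]]
           }, description = "realized senescence flux")

  ## ---- litterfall ----
  r <- add(r, "litterfall.raw_flux", "litterfall", "litterfall.raw_flux",
           c("vegetation.standing_dead_biomass", "vegetation.type"),
           function(ins, t, ctx) {
             litterfall_flux(ins[["vegetation.standing_dead_biomass"]],
                             .lookup(ins[["vegetation.type"]], vp, "litterfall_rate"))
           }, provenance = "table", description = "first-order litterfall")
  r <- add(r, "litterfall.dead_outflow_scale", "litterfall",
           "litterfall.dead_outflow_scale",
           c("vegetation.standing_dead_biomass", "senescence.flux",
             "litterfall.raw_flux", "ingestion.raw_intake_dead"),
           function(ins, t, ctx) {
             outflow_scale(ins[["vegetation.standing_dead_biomass"]],
                           ins[["senescence.flux"]],
                           ins[["litterfall.raw_flux"]] + ins[["ingestion.raw_intake_dead"]])
           }, description = "common rescale keeping the standing dead pool non-negative")
  r <- add(r, "litterfall.flux", "litterfall", "litterfall.flux",
           c("litterfall.raw_flux", "litterfall.dead_outflow_scale"),
           function(ins, t, ctx) {
             ins[["litterfall.raw_flux"]] * ins[["litterfall.dead_outflow_scale"]]
           }, description = "realized litterfall flux")
  r <- add(r, "litterfall.litter_decomposition", "litterfall",
           "litterfall.litter_decomposition",
           c("vegetation.litter_biomass", "temperature.limiting_factor",
             "moisture.limiting_factor", "vegetation.type"),
           function(ins, t, ctx) {
             ins[["vegetation.litter_biomass"]] *
               .lookup(ins[["vegetation.type"]], vp, "k_min") *
               ins[["temperature.limiting_factor"]] * ins[["moisture.limiting_factor"]]
           }, description = "litter mass loss, paired with N mineralization")
  r <- add(r, "litterfall.change_in_standing_dead_biomass", "litterfall",
           "litterfall.change_in_standing_dead_biomass",
           c("senescence.flux", "litterfall.flux", "ingestion.intake_dead"),
           function(ins, t, ctx) {
             ins[["senescence.flux"]] - ins[["litterfall.flux"]] -
               ins[["ingestion.intake_dead"]]
           },
           is_change_model = TRUE, of_concept = "vegetation.standing_dead_biomass",
           description = "daily balance of standing dead biomass")
  r <- add(r, "litterfall.change_in_litter_biomass", "litterfall",
           "litterfall.change_in_litter_biomass",
           c("litterfall.flux", "litterfall.litter_decomposition"),
           function(ins, t, ctx) {
             ins[["litterfall.flux"]] - ins[["litterfall.litter_decomposition"]]
           },
           is_change_model = TRUE, of_concept = "vegetation.litter_biomass",
           description = "daily balance of litter biomass")

  ## ---- ingestion ----
  groups <- if (nrow(lp)) split(lp, seq_len(nrow(lp))) else list()
  density_concepts <- if (nrow(lp)) paste0("livestock.density.", lp$group_id) else character(0)
  for (dc in density_concepts) {
    r <- register_concept(r, concept(dc, "animals per cell", "animal/cell"))
    r <- declare_external(r, dc)
  }
  r <- add(r, "ingestion.accessibility_cattle", "ingestion",
           "ingestion.accessibility_cattle", c("terrain.slope"),
           function(ins, t, ctx) accessibility(ins[["terrain.slope"]], "cattle"),
           description = "slope accessibility for cattle")
  r <- add(r, "ingestion.accessibility_mare", "ingestion",
           "ingestion.accessibility_mare", c("terrain.slope"),
           function(ins, t, ctx) accessibility(ins[["terrain.slope"]], "mare"),
           description = "slope accessibility for mares")

  group_demand <- function(g, ins, ctx) {
    acc <- ins[[paste0("ingestion.accessibility_", g$species)]]
    dens <- ins[[paste0("livestock.density.", g$group_id)]]
    dens / ctx$grid$cell_size^2 * g$intake_max * acc
  }
  r <- add(r, "ingestion.total_demand", "ingestion", "ingestion.total_demand",
           c("ingestion.accessibility_cattle", "ingestion.accessibility_mare",
             density_concepts),
           function(ins, t, ctx) {
             d <- 0
             for (g in groups) d <- d + group_demand(g, ins, ctx)
             if (is.matrix(d)) d else matrix(d, ctx$grid$nrows, ctx$grid$ncols)
           }, description = "summed grazing demand of all groups, g/m2/day")
  r <- add(r, "ingestion.raw_intake_living", "ingestion",
           "ingestion.raw_intake_living",
           c("ingestion.total_demand", "vegetation.living_biomass",
             "vegetation.standing_dead_biomass", "vegetation.type"),
           function(ins, t, ctx) {
             res <- ingestion(ins[["vegetation.living_biomass"]],
                              ins[["vegetation.standing_dead_biomass"]],
                              .lookup(ins[["vegetation.type"]], vp, "palatability"),
                              list(ins[["ingestion.total_demand"]]))
             res$intake_living
           }, description = "living biomass intake before pool limitation")
  r <- add(r, "ingestion.raw_intake_dead", "ingestion",
           "ingestion.raw_intake_dead",
           c("ingestion.total_demand", "vegetation.living_biomass",
             "vegetation.standing_dead_biomass", "vegetation.type"),
           function(ins, t, ctx) {
             res <- ingestion(ins[["vegetation.living_biomass"]],
                              ins[["vegetation.standing_dead_biomass"]],
                              .lookup(ins[["vegetation.type"]], vp, "palatability"),
                              list(ins[["ingestion.total_demand"]]))
             res$intake_dead
           }, description = "standing dead intake before pool limitation")
  r <- add(r, "ingestion.intake_living", "ingestion", "ingestion.intake_living",
           c("ingestion.raw_intake_living", "vegetation_growth.living_outflow_scale"),
           function(ins, t, ctx) {
             ins[["ingestion.raw_intake_living"]] *
               ins[["vegetation_growth.living_outflow_scale"]]
           }, description = "realized living biomass intake")
  r <- add(r, "ingestion.intake_dead", "ingestion", "ingestion.intake_dead",
           c("ingestion.raw_intake_dead", "litterfall.dead_outflow_scale"),
           function(ins, t, ctx) {
             ins[["ingestion.raw_intake_dead"]] * ins[["litterfall.dead_outflow_scale"]]
           }, description = "realized standing dead intake")
  r <- add(r, "ingestion.intake_total", "ingestion", "ingestion.intake_total",
           c("ingestion.intake_living", "ingestion.intake_dead"),
           function(ins, t, ctx) {
             ins[["ingestion.intake_living"]] + ins[["ingestion.intake_dead"]]
           }, description = "total realized intake")
  r <- add(r, "ingestion.satisfaction", "ingestion", "ingestion.satisfaction",
           c("ingestion.intake_total", "ingestion.total_demand"),
           function(ins, t, ctx) {
             d <- ins[["ingestion.total_demand"]]
             ifelse(d > 0, ins[["ingestion.intake_total"]] / d, 1)
           }, description = "fraction of demand met (competition is proportional)")

  ## ---- per-group ingestion / livestock mass ----
  for (g in groups) {
    gid <- g$group_id
    dens_c <- paste0("livestock.density.", gid)
    acc_c <- paste0("ingestion.accessibility_", g$species)
    weight_c <- paste0("livestock.weight.", gid)
    r <- register_concept(r, concept(weight_c, sprintf("mean body weight, group %s", gid), "kg"))
    r <- declare_external(r, weight_c)
    local({
      g <- g; gid <- gid; dens_c <- dens_c; acc_c <- acc_c; weight_c <- weight_c
      r <<- add(r, paste0("ingestion.intake_per_animal.", gid), "ingestion",
                paste0("ingestion.intake_per_animal.", gid),
                c("ingestion.satisfaction", acc_c, dens_c),
                function(ins, t, ctx) {
                  ifelse(ins[[dens_c]] > 0,
                         ins[["ingestion.satisfaction"]] * g$intake_max * ins[[acc_c]],
                         0)
                }, description = sprintf("per-animal intake, group %s (g/animal/day)", gid))
      r <<- add(r, paste0("livestock_mass.digestible_intake.", gid), "livestock_mass",
                paste0("livestock_mass.digestible_intake.", gid),
                c(paste0("ingestion.intake_per_animal.", gid), "vegetation.type"),
                function(ins, t, ctx) {
                  digestion(ins[[paste0("ingestion.intake_per_animal.", gid)]],
                            .lookup(ins[["vegetation.type"]], vp, "digestibility"))$digestible
                }, provenance = "table",
                description = sprintf("digestible intake, group %s", gid))
      r <<- add(r, paste0("livestock_mass.change_in_", gid), "livestock_mass",
                paste0("livestock_mass.change_in_", gid),
                c(paste0("livestock_mass.digestible_intake.", gid), weight_c, dens_c),
                function(ins, t, ctx) {
                  ifelse(ins[[dens_c]] > 0,
                         mass_change(ins[[paste0("livestock_mass.digestible_intake.", gid)]],
                                     ins[[weight_c]], g$conversion_eff,
                                     g$maintenance_coeff),
                         0)
                },
                is_change_model = TRUE, of_concept = weight_c,
                description = sprintf("daily weight change, group %s (kg/day)", gid))
    })
  }
  r <- add(r, "livestock_mass.living_fraction_of_intake", "livestock_mass",
           "livestock_mass.living_fraction_of_intake",
           c("ingestion.intake_living", "ingestion.intake_total"),
           function(ins, t, ctx) {
             tot <- ins[["ingestion.intake_total"]]
             ifelse(tot > 0, ins[["ingestion.intake_living"]] / tot, 0)
           }, description = "proportion of living biomass in digestion")

  ## ---- nitrogen (concentrations, uptake, leaching, pools) ----
  r <- add(r, "nitrogen.living_concentration", "nitrogen",
           "nitrogen.living_concentration",
           c("nitrogen.living_n", "vegetation.living_biomass"),
           function(ins, t, ctx) {
             b <- ins[["vegetation.living_biomass"]]
             ifelse(b > 0, ins[["nitrogen.living_n"]] / b, 0)
           }, description = "proportion of nitrogen in living biomass")
  r <- add(r, "nitrogen.dead_concentration", "nitrogen",
           "nitrogen.dead_concentration",
           c("nitrogen.standing_dead_n", "vegetation.standing_dead_biomass"),
           function(ins, t, ctx) {
             b <- ins[["vegetation.standing_dead_biomass"]]
             ifelse(b > 0, ins[["nitrogen.standing_dead_n"]] / b, 0)
           }, description = "proportion of nitrogen in standing dead biomass")
  r <- add(r, "nitrogen.mineralization", "nitrogen", "nitrogen.mineralization",
           c("nitrogen.litter_organic_n", "temperature.limiting_factor",
             "moisture.limiting_factor", "vegetation.type"),
           function(ins, t, ctx) {
             mineralization(ins[["nitrogen.litter_organic_n"]],
                            .lookup(ins[["vegetation.type"]], vp, "k_min"),
                            ins[["temperature.limiting_factor"]],
                            ins[["moisture.limiting_factor"]])
           }, provenance = "table",
           description = "first-order mineralization modulated by FT and FH")
  r <- add(r, "nitrogen.uptake_demand", "nitrogen", "nitrogen.uptake_demand",
           c("vegetation_growth.potential_growth", "vegetation.type"),
           function(ins, t, ctx) {
             ins[["vegetation_growth.potential_growth"]] *
               .lookup(ins[["vegetation.type"]], vp, "n_conc_target")
           }, description = "N demand of potential growth")
  r <- add(r, "nitrogen.credit_used", "nitrogen", "nitrogen.credit_used",
           c("nitrogen.uptake_demand", "nitrogen.reabsorption_credit"),
           function(ins, t, ctx) {
             pmin(ins[["nitrogen.uptake_demand"]], ins[["nitrogen.reabsorption_credit"]])
           }, description = "reabsorption credit applied against demand")
  r <- add(r, "nitrogen.raw_uptake", "nitrogen", "nitrogen.raw_uptake",
           c("nitrogen.uptake_demand", "nitrogen.credit_used", "nitrogen.soil_mineral_n"),
           function(ins, t, ctx) {
             pmin(pmax(ins[["nitrogen.uptake_demand"]] - ins[["nitrogen.credit_used"]], 0),
                  ins[["nitrogen.soil_mineral_n"]])
           }, description = "soil uptake before joint pool limitation")
  r <- add(r, "nitrogen.raw_leaching", "nitrogen", "nitrogen.raw_leaching",
           c("nitrogen.soil_mineral_n", "moisture.drainage", "vegetation.type"),
           function(ins, t, ctx) {
             leaching(ins[["nitrogen.soil_mineral_n"]], ins[["moisture.drainage"]],
                      .lookup(ins[["vegetation.type"]], vp, "whc"))
           }, description = "drainage-proportional leaching before pool limitation")
  r <- add(r, "nitrogen.mineral_outflow_scale", "nitrogen",
           "nitrogen.mineral_outflow_scale",
           c("nitrogen.soil_mineral_n", "nitrogen.raw_uptake", "nitrogen.raw_leaching"),
           function(ins, t, ctx) {
             # same-day inflows deliberately ignored: conservative but acyclic
             outflow_scale(ins[["nitrogen.soil_mineral_n"]], 0,
                           ins[["nitrogen.raw_uptake"]] + ins[["nitrogen.raw_leaching"]])
           }, description = "common rescale keeping the mineral pool non-negative")
  r <- add(r, "nitrogen.uptake", "nitrogen", "nitrogen.uptake",
           c("nitrogen.raw_uptake", "nitrogen.mineral_outflow_scale"),
           function(ins, t, ctx) {
             ins[["nitrogen.raw_uptake"]] * ins[["nitrogen.mineral_outflow_scale"]]
           }, description = "realized plant uptake of soil mineral N")
  r <- add(r, "nitrogen.leaching", "nitrogen", "nitrogen.leaching",
           c("nitrogen.raw_leaching", "nitrogen.mineral_outflow_scale"),
           function(ins, t, ctx) {
             ins[["nitrogen.raw_leaching"]] * ins[["nitrogen.mineral_outflow_scale"]]
           }, description = "realized nitrogen leaching")
  r <- add(r, "nitrogen.limiting_factor", "nitrogen", "nitrogen.limiting_factor",
           c("nitrogen.uptake", "nitrogen.credit_used", "nitrogen.uptake_demand"),
           function(ins, t, ctx) {
             d <- ins[["nitrogen.uptake_demand"]]
             fn <- ifelse(d > 0, (ins[["nitrogen.uptake"]] + ins[["nitrogen.credit_used"]]) / d, 1)
             pmin(1, pmax(0, fn))
           }, description = "nitrogen limiting factor FN = supplied / demanded")
  r <- add(r, "nitrogen.raw_senesced_n", "nitrogen", "nitrogen.raw_senesced_n",
           c("senescence.flux", "nitrogen.living_concentration"),
           function(ins, t, ctx) {
             ins[["senescence.flux"]] * ins[["nitrogen.living_concentration"]]
           }, description = "N in senescing tissue before pool limitation")
  r <- add(r, "nitrogen.raw_ingested_living_n", "nitrogen",
           "nitrogen.raw_ingested_living_n",
           c("ingestion.intake_living", "nitrogen.living_concentration"),
           function(ins, t, ctx) {
             ins[["ingestion.intake_living"]] * ins[["nitrogen.living_concentration"]]
           }, description = "N in grazed living biomass before pool limitation")
  r <- add(r, "nitrogen.raw_ingested_dead_n", "nitrogen",
           "nitrogen.raw_ingested_dead_n",
           c("ingestion.intake_dead", "nitrogen.dead_concentration"),
           function(ins, t, ctx) {
             ins[["ingestion.intake_dead"]] * ins[["nitrogen.dead_concentration"]]
           }, description = "N in grazed standing dead biomass before pool limitation")
  r <- add(r, "nitrogen.living_n_outflow_scale", "nitrogen",
           "nitrogen.living_n_outflow_scale",
           c("nitrogen.living_n", "nitrogen.uptake", "nitrogen.credit_used",
             "nitrogen.raw_senesced_n", "nitrogen.raw_ingested_living_n"),
           function(ins, t, ctx) {
             outflow_scale(ins[["nitrogen.living_n"]],
                           ins[["nitrogen.uptake"]] + ins[["nitrogen.credit_used"]],
                           ins[["nitrogen.raw_senesced_n"]] +
                             ins[["nitrogen.raw_ingested_living_n"]])
           }, description = "common rescale keeping the living N pool non-negative")
  r <- add(r, "nitrogen.senesced_n", "nitrogen", "nitrogen.senesced_n",
           c("nitrogen.raw_senesced_n", "nitrogen.living_n_outflow_scale"),
           function(ins, t, ctx) {
             ins[["nitrogen.raw_senesced_n"]] * ins[["nitrogen.living_n_outflow_scale"]]
           }, description = "realized senesced N")
  r <- add(r, "nitrogen.ingested_living_n", "nitrogen", "nitrogen.ingested_living_n",
           c("nitrogen.raw_ingested_living_n", "nitrogen.living_n_outflow_scale"),
           function(ins, t, ctx) {
             ins[["nitrogen.raw_ingested_living_n"]] *
               ins[["nitrogen.living_n_outflow_scale"]]
           }, description = "realized N intake from living biomass")
  r <- add(r, "nitrogen.reabsorbed", "nitrogen", "nitrogen.reabsorbed",
           c("nitrogen.senesced_n", "vegetation.type"),
           function(ins, t, ctx) {
             ins[["nitrogen.senesced_n"]] *
               .lookup(ins[["vegetation.type"]], vp, "reabs_fraction")
           }, provenance = "table",
           description = "N withdrawn from senescing tissue into the plant budget")
  r <- add(r, "nitrogen.to_dead_n", "nitrogen", "nitrogen.to_dead_n",
           c("nitrogen.senesced_n", "nitrogen.reabsorbed"),
           function(ins, t, ctx) {
             ins[["nitrogen.senesced_n"]] - ins[["nitrogen.reabsorbed"]]
           }, description = "senesced N moving to the standing dead pool")
  r <- add(r, "nitrogen.raw_litterfall_n", "nitrogen", "nitrogen.raw_litterfall_n",
           c("litterfall.flux", "nitrogen.dead_concentration"),
           function(ins, t, ctx) {
             ins[["litterfall.flux"]] * ins[["nitrogen.dead_concentration"]]
           }, description = "N in litterfall before pool limitation")
  r <- add(r, "nitrogen.dead_n_outflow_scale", "nitrogen",
           "nitrogen.dead_n_outflow_scale",
           c("nitrogen.standing_dead_n", "nitrogen.to_dead_n",
             "nitrogen.raw_litterfall_n", "nitrogen.raw_ingested_dead_n"),
           function(ins, t, ctx) {
             outflow_scale(ins[["nitrogen.standing_dead_n"]], ins[["nitrogen.to_dead_n"]],
                           ins[["nitrogen.raw_litterfall_n"]] +
                             ins[["nitrogen.raw_ingested_dead_n"]])
           }, description = "common rescale keeping the dead N pool non-negative")
  r <- add(r, "nitrogen.litterfall_n", "nitrogen", "nitrogen.litterfall_n",
           c("nitrogen.raw_litterfall_n", "nitrogen.dead_n_outflow_scale"),
           function(ins, t, ctx) {
             ins[["nitrogen.raw_litterfall_n"]] * ins[["nitrogen.dead_n_outflow_scale"]]
           }, description = "realized litterfall N")
  r <- add(r, "nitrogen.ingested_dead_n", "nitrogen", "nitrogen.ingested_dead_n",
           c("nitrogen.raw_ingested_dead_n", "nitrogen.dead_n_outflow_scale"),
           function(ins, t, ctx) {
             ins[["nitrogen.raw_ingested_dead_n"]] * ins[["nitrogen.dead_n_outflow_scale"]]
           }, description = "realized N intake from standing dead biomass")

  ## ---- excretion ----
  r <- add(r, "excretion.ingested_nitrogen", "excretion", "excretion.ingested_nitrogen",
           c("nitrogen.ingested_living_n", "nitrogen.ingested_dead_n"),
           function(ins, t, ctx) {
             ins[["nitrogen.ingested_living_n"]] + ins[["nitrogen.ingested_dead_n"]]
           }, description = "total N ingested by livestock")
  excreta_weights <- function(ins, ctx) {
    # demand-share weighted retention and solid fraction across groups
    tot <- 0; wr <- 0; ws <- 0
    for (g in groups) {
      d <- group_demand(g, ins, ctx)
      tot <- tot + d
      wr <- wr + d * g$n_retention
      ws <- ws + d * g$solid_fraction
    }
    if (!length(groups)) {
      z <- matrix(0, ctx$grid$nrows, ctx$grid$ncols)
      return(list(retention = z, solid = z))
    }
    list(retention = ifelse(tot > 0, wr / tot, 0),
         solid = ifelse(tot > 0, ws / tot, 0))
  }
  excreta_inputs <- c("excretion.ingested_nitrogen",
                      "ingestion.accessibility_cattle",
                      "ingestion.accessibility_mare", density_concepts)
  r <- add(r, "excretion.solid_nitrogen", "excretion", "excretion.solid_nitrogen",
           excreta_inputs,
           function(ins, t, ctx) {
             w <- excreta_weights(ins, ctx)
             excretion(ins[["excretion.ingested_nitrogen"]], w$retention, w$solid)$solid
           }, description = "N returned in solid manure")
  r <- add(r, "excretion.urine_nitrogen", "excretion", "excretion.urine_nitrogen",
           excreta_inputs,
           function(ins, t, ctx) {
             w <- excreta_weights(ins, ctx)
             excretion(ins[["excretion.ingested_nitrogen"]], w$retention, w$solid)$urine
           }, description = "N returned in urine")
  r <- add(r, "excretion.retained_nitrogen", "excretion", "excretion.retained_nitrogen",
           c("excretion.ingested_nitrogen", "excretion.solid_nitrogen",
             "excretion.urine_nitrogen"),
           function(ins, t, ctx) {
             ins[["excretion.ingested_nitrogen"]] - ins[["excretion.solid_nitrogen"]] -
               ins[["excretion.urine_nitrogen"]]
           }, description = "N retained by the animals")
  r <- add(r, "excretion.n_in_living_biomass_from_solid_manure", "excretion",
           "excretion.n_in_living_biomass_from_solid_manure",
           c("ingestion.intake_living", "livestock_mass.living_fraction_of_intake",
             "nitrogen.living_concentration"),
           function(ins, t, ctx) {
             n_in_biomass_from_solid_manure(
               ins[["ingestion.intake_living"]],
               ins[["livestock_mass.living_fraction_of_intake"]],
               ins[["nitrogen.living_concentration"]]
             )
           }, description = "cross-namespace chain: living intake x digestion share x N proportion")

  ## ---- nitrogen pool change models ----
  r <- add(r, "nitrogen.change_in_soil_mineral_n", "nitrogen",
           "nitrogen.change_in_soil_mineral_n",
           c("nitrogen.mineralization", "excretion.urine_nitrogen",
             "nitrogen.fertilization", "nitrogen.uptake", "nitrogen.leaching"),
           function(ins, t, ctx) {
             ins[["nitrogen.mineralization"]] + ins[["excretion.urine_nitrogen"]] +
               ins[["nitrogen.fertilization"]] - ins[["nitrogen.uptake"]] -
               ins[["nitrogen.leaching"]]
           },
           is_change_model = TRUE, of_concept = "nitrogen.soil_mineral_n",
           description = "daily balance of soil mineral N")
  r <- add(r, "nitrogen.change_in_litter_organic_n", "nitrogen",
           "nitrogen.change_in_litter_organic_n",
           c("nitrogen.litterfall_n", "excretion.solid_nitrogen",
             "nitrogen.mineralization"),
           function(ins, t, ctx) {
             ins[["nitrogen.litterfall_n"]] + ins[["excretion.solid_nitrogen"]] -
               ins[["nitrogen.mineralization"]]
           },
           is_change_model = TRUE, of_concept = "nitrogen.litter_organic_n",
           description = "daily balance of litter organic N")
  r <- add(r, "nitrogen.change_in_living_n", "nitrogen", "nitrogen.change_in_living_n",
           c("nitrogen.uptake", "nitrogen.credit_used", "nitrogen.senesced_n",
             "nitrogen.ingested_living_n"),
           function(ins, t, ctx) {
             ins[["nitrogen.uptake"]] + ins[["nitrogen.credit_used"]] -
               ins[["nitrogen.senesced_n"]] - ins[["nitrogen.ingested_living_n"]]
           },
           is_change_model = TRUE, of_concept = "nitrogen.living_n",
           description = "daily balance of N in living biomass")
  r <- add(r, "nitrogen.change_in_standing_dead_n", "nitrogen",
           "nitrogen.change_in_standing_dead_n",
           c("nitrogen.to_dead_n", "nitrogen.litterfall_n", "nitrogen.ingested_dead_n"),
           function(ins, t, ctx) {
             ins[["nitrogen.to_dead_n"]] - ins[["nitrogen.litterfall_n"]] -
               ins[["nitrogen.ingested_dead_n"]]
           },
           is_change_model = TRUE, of_concept = "nitrogen.standing_dead_n",
           description = "daily balance of N in standing dead biomass")
  r <- add(r, "nitrogen.change_in_reabsorption_credit", "nitrogen",
           "nitrogen.change_in_reabsorption_credit",
           c("nitrogen.reabsorbed", "nitrogen.credit_used"),
           function(ins, t, ctx) {
             ins[["nitrogen.reabsorbed"]] - ins[["nitrogen.credit_used"]]
           },
           is_change_model = TRUE, of_concept = "nitrogen.reabsorption_credit",
           description = "carry-over of reabsorbed N to next-step demand")

  r
}
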