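#' Assemble engine inputs from a landscape
#'
#' Maps the artifacts of a [generate_landscape()] (or [read_landscape()])
#' bundle onto the external input concepts of the default registry: climate
#' series, terrain, vegetation maps, per-group densities and the
#' initialization fields of every state concept.
#'
#' @param landscape A `pal_landscape`.
#' @param init Optional named list overriding default initial states. The
#'   defaults are: soil water at 70% of capacity, 150 g/m2 living biomass,
#'   50 g/m2 standing dead, 100 g/m2 litter, 5 g N/m2 soil mineral N, litter
#'   organic N at 1.5% of litter mass, living N at the type's target
#'   concentration, dead N at 1% of the dead pool, zero reabsorption credit,
#'   group weights at their parameter means.
#' @param harvest Daily harvest-fraction input (scalar, series or function;
#'   default 0).
#' @param fertilization Daily fertilization input (g N/m2/day; default 0).
#' @return Named list of inputs for [execute()].
#' @export
pal_inputs <- function(landscape, init = list(), harvest = 0, fertilization = 0) {
  vp <- landscape$vegetation_params
  com <- landscape$vegetation$values
  whc <- .lookup(com, vp, "whc")
  nconc <- .lookup(com, vp, "n_conc_target")
  clim <- landscape$climate

  defaults <- list(
    "moisture.soil_water" = 0.7 * whc,
    "vegetation.living_biomass" = 150,
    "vegetation.standing_dead_biomass" = 50,
    "vegetation.litter_biomass" = 100,
    "nitrogen.soil_mineral_n" = 5,
    "nitrogen.litter_organic_n" = 100 * 0.015,
    "nitrogen.living_n" = 150 * nconc,
    "nitrogen.standing_dead_n" = 50 * 0.01,
    "nitrogen.reabsorption_credit" = 0
  )
  for (nm in names(init)) defaults[[nm]] <- init[[nm]]

  inputs <- c(
    list(
      "climate.tmean" = tibble::tibble(date = clim$date, value = clim$tmean_c),
      "climate.precip" = tibble::tibble(date = clim$date, value = clim$precip_mm),
      "climate.rg" = tibble::tibble(date = clim$date, value = clim$rg_mj_m2),
      "terrain.slope" = landscape$slope,
      "terrain.exposure" = 1,
      "vegetation.type" = landscape$vegetation,
      "vegetation.overstory_type" = landscape$overstory,
      "vegetation.harvest_fraction" = harvest,
      "nitrogen.fertilization" = fertilization
    ),
    defaults
  )
  for (gid in names(landscape$livestock_densities)) {
    inputs[[paste0("livestock.density.", gid)]] <- landscape$livestock_densities[[gid]]
  }
  lp <- landscape$livestock_params
  for (i in seq_len(nrow(lp))) {
    inputs[[paste0("livestock.weight.", lp$group_id[i])]] <- lp$mean_weight[i]
  }
  inputs
}

#' Resolve and execute a query over a landscape
#'
#' The one-call front end: builds (or accepts) the registry, constructs the
#' context from the landscape grid and the climate series, resolves the
#' query and executes the dataflow.
#'
#' @param landscape A `pal_landscape`.
#' @param query Concept id(s) to compute, or `"all"` for every concept the
#'   registry can produce.
#' @param start,end Timeline bounds; default to the climate series range.
#' @param registry Optional prebuilt `pal_registry`; by default built from
#'   the landscape's parameter tables.
#' @param inputs Optional prebuilt inputs (see [pal_inputs()]).
#' @param ... Passed to [pal_inputs()].
#' @return A list of class `pal_run` with `store`, `dataflow`, `context`,
#'   `registry`, `landscape`.
#' @export
pal_run <- function(landscape, query = "vegetation.living_biomass",
                    start = NULL, end = NULL, registry = NULL,
                    inputs = NULL, ...) {
  if (is.null(registry)) {
    registry <- pal_default_registry(landscape$vegetation_params,
                                     landscape$livestock_params)
  }
  if (is.null(start)) start <- min(landscape$climate$date)
  if (is.null(end)) end <- max(landscape$climate$date)
  ctx <- context(landscape$grid, timeline(start, end))
  if (identical(query, "all")) {
    # change-model outputs are pulled in by dynamization, not queried directly
    statics <- Filter(function(c) !c$is_change_model, registry$components)
    query <- sort(unique(c(
      vapply(statics, `[[`, character(1), "output"),
      registry$externals
    )))
  }
  if (is.null(inputs)) inputs <- pal_inputs(landscape, ...)
  df <- resolve(query, registry, ctx)
  store <- execute(df, ctx, inputs)
  structure(
    list(store = store, dataflow = df, context = ctx, registry = registry,
         landscape = landscape),
    class = "pal_run"
  )
}

#' @export
print.pal_run <- function(x, ...) {
  print(x$dataflow)
  print(x$store)
  invisible(x)
}

#' Convert a management event table into a daily input series
#'
#' Events (harvest fractions or fertilization amounts on given dates, per
#' vegetation zone) become a `function(t, context)` input: zero everywhere
#' except the event dates, where the event value is placed on the cells of
#' the named zone (`zone_id = NA` applies everywhere).
#'
#' @param events Tibble with columns `date`, `zone_id`, `kind`
#'   (`"harvest"` or `"fertilization"`), `fraction_or_amount`.
#' @param zones Categorical `pal_field` of zone codes (the vegetation map or
#'   any management-unit raster).
#' @param kind Which event kind to extract.
#' @return A function usable as an engine input.
#' @export
events_to_series <- function(events, zones, kind = c("harvest", "fertilization")) {
  kind <- match.arg(kind)
  events <- events[events$kind == kind, , drop = FALSE]
  events$date <- as.Date(events$date)
  function(t, context) {
    d <- timeline_dates(context$timeline)[t]
    m <- matrix(0, context$grid$nrows, context$grid$ncols)
    todays <- events[events$date == d, , drop = FALSE]
    for (i in seq_len(nrow(todays))) {
      if (is.na(todays$zone_id[i])) {
        m[] <- m + todays$fraction_or_amount[i]
      } else {
        sel <- !is.na(zones$values) & zones$values == todays$zone_id[i]
        m[sel] <- m[sel] + todays$fraction_or_amount[i]
      }
    }
    if (kind == "harvest") m <- pmin(m, 1)
    m
  }
}

#' Per-step budget diagnostics of a full run
#'
#' Recomputes, from the stored fields of a run, the daily closure of the
#' biomass balance and of the whole-system nitrogen budget. Used by the
#' conservation tests and available for run QC.
#'
#' @param run A `pal_run` whose query included the pools and fluxes
#'   (`query = "all"` is simplest).
#' @return A tibble with one row per step transition: `step`,
#'   `biomass_residual` and `nitrogen_residual` (g m-2, maximum absolute
#'   cell residual), plus the pool totals.
#' @export
pal_budget <- function(run) {
  st <- run$store
  n <- run$context$timeline$n_steps
  gf <- function(cid, t) get_field(st, cid, t, as_field = FALSE)
  pools_b <- c("vegetation.living_biomass", "vegetation.standing_dead_biomass",
               "vegetation.litter_biomass")
  pools_n <- c("nitrogen.soil_mineral_n", "nitrogen.litter_organic_n",
               "nitrogen.living_n", "nitrogen.standing_dead_n",
               "nitrogen.reabsorption_credit")
  purrr::map_dfr(seq_len(n - 1), function(t) {
    db <- Reduce(`+`, lapply(pools_b, function(p) gf(p, t + 1) - gf(p, t)))
    flux_b <- gf("vegetation_growth.actual_growth", t) -
      gf("vegetation_growth.harvest", t) -
      gf("ingestion.intake_living", t) - gf("ingestion.intake_dead", t) -
      gf("litterfall.litter_decomposition", t)
    dn <- Reduce(`+`, lapply(pools_n, function(p) gf(p, t + 1) - gf(p, t)))
    flux_n <- gf("nitrogen.fertilization", t) - gf("nitrogen.leaching", t) -
      gf("excretion.retained_nitrogen", t)
    tibble::tibble(
      step = t,
      biomass_residual = max(abs(db - flux_b)),
      nitrogen_residual = max(abs(dn - flux_n)),
      biomass_total = sum(Reduce(`+`, lapply(pools_b, gf, t = t + 1))),
      nitrogen_total = sum(Reduce(`+`, lapply(pools_n, gf, t = t + 1)))
    )
  })
}
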