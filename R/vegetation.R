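#' Potential vegetation growth
#'
#' The growth core: daily potential above-ground biomass growth is the
#' vegetation type's maximum daily growth scaled by the combined abiotic
#' factor and the phenological activity, `xf * ftrh * ph`, exactly.
#'
#' @param xf Maximum daily growth, g m-2 day-1.
#' @param ftrh Combined abiotic limiting factor in \[0, 1\].
#' @param ph Phenology activity in \[0, 1\].
#' @return Potential growth, g m-2 day-1.
#' @export
potential_growth <- function(xf, ftrh, ph) {
  xf * ftrh * ph
}

#' Actual vegetation growth
#'
#' Potential growth scaled by the nitrogen limiting factor. The influence of
#' livestock enters separately, as the ingestion flux removed from the
#' biomass pool, not as a growth-rate modifier.
#'
#' @param potential Potential growth, g m-2 day-1.
#' @param fn Nitrogen limiting factor in \[0, 1\].
#' @return Actual growth, g m-2 day-1 (always `<= potential`).
#' @export
actual_growth <- function(potential, fn) {
  potential * fn
}

#' Senescence flux
#'
#' First-order transfer from living to standing-dead biomass, modulated by
#' phenology so senescence peaks when activity is low:
#' `flux = agb_living * rate * (1 - ph)`.
#'
#' @param agb_living Living above-ground biomass, g m-2.
#' @param rate Senescence rate, day-1, in \[0, 1\].
#' @param ph Phenology activity in \[0, 1\].
#' @return Flux, g m-2 day-1.
#' @export
senescence_flux <- function(agb_living, rate, ph) {
  agb_living * rate * (1 - ph)
}

#' Litterfall flux
#'
#' First-order transfer from standing dead biomass to litter.
#'
#' @param agb_dead Standing dead biomass, g m-2.
#' @param rate Litterfall rate, day-1, in \[0, 1\].
#' @return Flux, g m-2 day-1.
#' @export
litterfall_flux <- function(agb_dead, rate) {
  agb_dead * rate
}

#' Apply a harvest event
#'
#' Removes a fraction of the living biomass on an event date.
#'
#' @param state List with `agb_living`, `agb_dead`, `litter` (g m-2).
#' @param fraction Fraction removed, in \[0, 1\] (vectorized per cell).
#' @return List with the updated `state` and the removed `flux` (g m-2).
#' @export
apply_harvest <- function(state, fraction) {
  flux <- state$agb_living * fraction
  state$agb_living <- state$agb_living - flux
  list(state = state, flux = flux)
}

# Proportional rescaling of outflows so a pool stays non-negative:
# out_total <= pool + inflow. Returns the common scale factor in [0, 1].
outflow_scale <- function(pool, inflow, out_total) {
  avail <- pool + inflow
  s <- ifelse(out_total > avail & out_total > 0, avail / out_total, 1)
  pmin(1, pmax(0, s))
}

#' Update vegetation pools for one day
#'
#' Applies growth, senescence, harvest, ingestion, litterfall and litter
#' decomposition to the three biomass pools. When demanded outflows exceed a
#' pool plus its inflow, all outflows from that pool are rescaled by a common
#' factor so the pool stays non-negative and the daily mass balance still
#' closes exactly.
#'
#' @param state List with `agb_living`, `agb_dead`, `litter` (g m-2 each,
#'   vectorized).
#' @param fluxes List with `actual_growth`, `senescence`, `harvest`,
#'   `litterfall`, `decomposition` (g m-2 day-1; missing entries default 0).
#' @param ingestion_living,ingestion_dead Grazed biomass, g m-2 day-1.
#' @return List with the updated `state` and the `realized` fluxes after
#'   rescaling (same names as `fluxes` plus `ingestion_living`,
#'   `ingestion_dead`).
#' @export
update_vegetation <- function(state, fluxes, ingestion_living = 0,
                              ingestion_dead = 0) {
  f <- function(name) if (is.null(fluxes[[name]])) 0 else fluxes[[name]]
  growth <- f("actual_growth"); sen <- f("senescence"); harv <- f("harvest")
  litt <- f("litterfall"); dec <- f("decomposition")

  s_liv <- outflow_scale(state$agb_living, growth, sen + harv + ingestion_living)
  sen_r <- sen * s_liv; harv_r <- harv * s_liv; ing_l_r <- ingestion_living * s_liv

  s_dead <- outflow_scale(state$agb_dead, sen_r, litt + ingestion_dead)
  litt_r <- litt * s_dead; ing_d_r <- ingestion_dead * s_dead

  s_lit <- outflow_scale(state$litter, litt_r, dec)
  dec_r <- dec * s_lit

  state$agb_living <- pmax(0, state$agb_living + growth - sen_r - harv_r - ing_l_r)
  state$agb_dead <- pmax(0, state$agb_dead + sen_r - litt_r - ing_d_r)
  state$litter <- pmax(0, state$litter + litt_r - dec_r)

  list(
    state = state,
    realized = list(
      actual_growth = growth, senescence = sen_r, harvest = harv_r,
      litterfall = litt_r, decomposition = dec_r,
      ingestion_living = ing_l_r, ingestion_dead = ing_d_r
    )
  )
}
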