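#' Litter nitrogen mineralization
#'
#' First-order release of mineral nitrogen from litter organic nitrogen,
#' modulated by the temperature and moisture limiting factors (mineralization
#' stops in frozen or dry soil): `flux = litter_n * k_min * FT * FH`.
#'
#' @param litter_organic_n Litter organic N pool, g N m-2.
#' @param k_min Mineralization rate constant, day-1, in \[0, 1\].
#' @param ft,fh Temperature and moisture limiting factors in \[0, 1\].
#' @return Flux, g N m-2 day-1 (never exceeds the pool).
#' @export
mineralization <- function(litter_organic_n, k_min, ft, fh) {
  litter_organic_n * k_min * ft * fh
}

#' Plant nitrogen uptake and the nitrogen limiting factor
#'
#' Demand is the potential growth times the target tissue N concentration,
#' reduced by any internally reabsorbed N credited from earlier senescence.
#' Soil uptake covers what the credit cannot; FN is the fraction of demand
#' met (1 when there is no demand).
#'
#' @param growth_potential Potential growth, g m-2 day-1.
#' @param n_conc_target Target N concentration, g N per g biomass.
#' @param soil_mineral_n Plant-available soil mineral N, g N m-2.
#' @param credit Reabsorption credit carried from previous steps, g N m-2.
#' @return List with `demand`, `credit_used`, `uptake`, `fn`.
#' @export
plant_uptake <- function(growth_potential, n_conc_target, soil_mineral_n,
                         credit = 0) {
  demand <- growth_potential * n_conc_target
  credit_used <- pmin(demand, credit)
  uptake <- pmin(pmax(demand - credit_used, 0), soil_mineral_n)
  fn <- ifelse(demand > 0, (uptake + credit_used) / demand, 1)
  list(demand = demand, credit_used = credit_used, uptake = uptake,
       fn = pmin(1, pmax(0, fn)))
}

#' Nitrogen reabsorption at senescence
#'
#' A fraction of the nitrogen in senescing tissue is withdrawn back into the
#' plant's internal budget (credited against future uptake demand); the rest
#' moves to the standing dead pool with the tissue.
#'
#' @param senescence Senescence biomass flux, g m-2 day-1.
#' @param n_conc_living N concentration of living biomass, g N per g.
#' @param reabs_fraction Reabsorbed fraction in \[0, 1\].
#' @return List with `n_senesced`, `reabsorbed`, `to_dead`.
#' @export
reabsorption <- function(senescence, n_conc_living, reabs_fraction) {
  n_senesced <- senescence * n_conc_living
  reabsorbed <- n_senesced * reabs_fraction
  list(n_senesced = n_senesced, reabsorbed = reabsorbed,
       to_dead = n_senesced - reabsorbed)
}

#' Nitrogen leaching
#'
#' Drainage-proportional loss of soil mineral nitrogen:
#' `flux = soil_mineral_n * min(1, drainage / whc)` — zero without drainage,
#' the whole pool when a full bucket volume drains.
#'
#' @param soil_mineral_n Soil mineral N pool, g N m-2.
#' @param drainage Bucket drainage, mm/day.
#' @param whc Water-holding capacity, mm.
#' @return Flux, g N m-2 day-1.
#' @export
leaching <- function(soil_mineral_n, drainage, whc) {
  soil_mineral_n * pmin(1, drainage / whc)
}

#' Update nitrogen pools for one day
#'
#' Applies mineralization, uptake (plus reabsorption credit use), senescence
#' transfer, litterfall transfer, ingestion removals, excreta returns,
#' fertilization and leaching to the nitrogen pools. Outflows from a pool are
#' rescaled by a common factor whenever they would drive it negative, exactly
#' as for the biomass pools, so the nitrogen budget still closes.
#'
#' @param pools List with `soil_mineral_n`, `litter_organic_n`, `n_living`,
#'   `n_dead`, `credit` (g N m-2 each, vectorized).
#' @param fluxes List with (all optional, default 0): `mineralization`,
#'   `uptake`, `credit_used`, `senesced_n`, `reabsorbed`, `litterfall_n`,
#'   `ingested_living_n`, `ingested_dead_n`, `solid_n`, `urine_n`,
#'   `fertilization`, `leaching`.
#' @return List with updated `pools` and the `realized` fluxes.
#' @export
update_nitrogen <- function(pools, fluxes) {
  f <- function(name) if (is.null(fluxes[[name]])) 0 else fluxes[[name]]
  mins <- f("mineralization"); upt <- f("uptake"); cred <- f("credit_used")
  sen_n <- f("senesced_n"); reab <- f("reabsorbed"); litt_n <- f("litterfall_n")
  ing_l <- f("ingested_living_n"); ing_d <- f("ingested_dead_n")
  solid <- f("solid_n"); urine <- f("urine_n")
  fert <- f("fertilization"); leach <- f("leaching")

  # soil mineral pool: joint cap on uptake + leaching
  s_min <- outflow_scale(pools$soil_mineral_n, mins + urine + fert, upt + leach)
  upt_r <- upt * s_min; leach_r <- leach * s_min
  cred_r <- cred  # credit use capped against the credit pool below

  # living N: outflows senesced + ingested, inflow uptake + credit used
  s_liv <- outflow_scale(pools$n_living, upt_r + cred_r, sen_n + ing_l)
  sen_n_r <- sen_n * s_liv; ing_l_r <- ing_l * s_liv
  reab_r <- ifelse(sen_n > 0, reab * sen_n_r / sen_n, 0)
  to_dead <- sen_n_r - reab_r

  # dead N: outflows litterfall + ingested, inflow senesced minus reabsorbed
  s_dead <- outflow_scale(pools$n_dead, to_dead, litt_n + ing_d)
  litt_n_r <- litt_n * s_dead; ing_d_r <- ing_d * s_dead

  # litter organic N: outflow mineralization, inflows litterfall + solid manure
  s_lit <- outflow_scale(pools$litter_organic_n, litt_n_r + solid, mins)
  mins_r <- mins * s_lit

  # reabsorption credit: outflow credit_used
  s_cred <- outflow_scale(pools$credit, reab_r, cred_r)
  cred_rr <- cred_r * s_cred

  pools$soil_mineral_n <- pmax(0, pools$soil_mineral_n + mins_r + urine + fert -
                                 upt_r - leach_r)
  pools$litter_organic_n <- pmax(0, pools$litter_organic_n + litt_n_r + solid - mins_r)
  pools$n_living <- pmax(0, pools$n_living + upt_r + cred_rr - sen_n_r - ing_l_r)
  pools$n_dead <- pmax(0, pools$n_dead + to_dead - litt_n_r - ing_d_r)
  pools$credit <- pmax(0, pools$credit + reab_r - cred_rr)

  list(
    pools = pools,
    realized = list(
      mineralization = mins_r, uptake = upt_r, credit_used = cred_rr,
      senesced_n = sen_n_r, reabsorbed = reab_r, to_dead_n = to_dead,
      litterfall_n = litt_n_r, ingested_living_n = ing_l_r,
      ingested_dead_n = ing_d_r, solid_n = solid, urine_n = urine,
      fertilization = fert, leaching = leach_r
    )
  )
}
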