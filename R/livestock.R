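#' Terrain accessibility for grazing
#'
#' Linear decline of grazing accessibility with slope: 1 at or below `s0`,
#' 0 at or above `s1`. Cattle thresholds sit strictly inside the mares'
#' thresholds, so cattle accessibility never exceeds mare accessibility —
#' cattle are the species more constrained by topography.
#'
#' @param slope Terrain slope, degrees (>= 0), vectorized.
#' @param species `"cattle"` or `"mare"`.
#' @param thresholds Named list of `c(s0, s1)` per species.
#' @return Accessibility fraction in \[0, 1\].
#' @export
accessibility <- function(slope, species = c("cattle", "mare"),
                          thresholds = accessibility_thresholds()) {
  species <- match.arg(species)
  th <- thresholds[[species]]
  pmin(1, pmax(0, (th[2] - slope) / (th[2] - th[1])))
}

#' @rdname accessibility
#' @export
accessibility_thresholds <- function() {
  list(cattle = c(10, 30), mare = c(15, 40))
}

#' Grazing intake with competition
#'
#' Per-cell forage allocation: each group demands
#' `density x intake_max x accessibility` (g m-2 day-1); the palatable supply
#' (living preferred over standing dead) is shared proportionally to demand
#' when it cannot satisfy everyone, so satisfaction is equal across competing
#' groups.
#'
#' @param agb_living,agb_dead Available biomass pools, g m-2.
#' @param palatability Fraction of each pool that is edible in one day.
#' @param demands Numeric vector (or list of matrices) of per-group demand,
#'   g m-2 day-1.
#' @return List with `intake_living`, `intake_dead`, `intake_total` (summed
#'   over groups), per-group `group_intake` and `satisfaction` (fraction of
#'   demand met; 1 where demand is zero).
#' @export
ingestion <- function(agb_living, agb_dead, palatability, demands) {
  if (!is.list(demands)) demands <- as.list(demands)
  demand_total <- Reduce(`+`, demands, accumulate = FALSE)
  supply_living <- palatability * agb_living
  supply_dead <- palatability * agb_dead
  supply <- supply_living + supply_dead
  intake_total <- pmin(demand_total, supply)
  satisfaction <- ifelse(demand_total > 0, intake_total / demand_total, 1)
  intake_living <- pmin(intake_total, supply_living)
  intake_dead <- intake_total - intake_living
  group_intake <- lapply(demands, function(d) d * satisfaction)
  list(
    intake_living = intake_living, intake_dead = intake_dead,
    intake_total = intake_total, group_intake = group_intake,
    satisfaction = satisfaction
  )
}

#' Digestion split
#'
#' Splits intake into digestible and indigestible fractions; the two always
#' sum back to the intake.
#'
#' @param intake Intake, g per animal per day (any non-negative quantity).
#' @param digestibility Digestible fraction in \[0, 1\].
#' @return List with `digestible` and `indigestible`.
#' @export
digestion <- function(intake, digestibility) {
  digestible <- intake * digestibility
  list(digestible = digestible, indigestible = intake - digestible)
}

#' Daily weight change
#'
#' Linear energy-balance surrogate on digestible dry matter: weight change is
#' the conversion efficiency times the surplus of digestible intake over
#' maintenance needs, which scale with body weight. Negative when intake
#' falls short of maintenance.
#'
#' @param digestible Digestible intake, g per animal per day.
#' @param weight Body weight, kg.
#' @param conversion_eff kg gain per g digestible intake surplus.
#' @param maintenance_coeff Maintenance requirement, g digestible biomass
#'   equivalent per kg body weight per day.
#' @return Weight change, kg per animal per day.
#' @export
mass_change <- function(digestible, weight, conversion_eff, maintenance_coeff) {
  conversion_eff * (digestible - maintenance_coeff * weight)
}

#' Excretion of ingested nitrogen
#'
#' Nitrogen not retained by the animal returns to the system, split between
#' solid manure and urine. Conservation holds exactly:
#' `retained + solid + urine = intake_n`.
#'
#' @param intake_n Ingested nitrogen, g N m-2 day-1.
#' @param n_retention Fraction of ingested N retained by the animal.
#' @param solid_fraction Fraction of excreted N in solid manure.
#' @return List with `solid`, `urine`, `retained`.
#' @export
excretion <- function(intake_n, n_retention, solid_fraction) {
  excreted <- intake_n * (1 - n_retention)
  list(
    solid = excreted * solid_fraction,
    urine = excreted * (1 - solid_fraction),
    retained = intake_n * n_retention
  )
}

#' Nitrogen in living biomass routed through solid manure
#'
#' The cross-namespace composition chain: living biomass ingested, times the
#' proportion of living biomass in digestion, times the proportion of
#' nitrogen in living biomass. The product is identical whether the three
#' component models are invoked standalone or inside a full dataflow.
#'
#' @param intake_living Living biomass ingestion, g m-2 day-1.
#' @param prop_living_in_digestion Fraction of digestion from living biomass.
#' @param prop_n_living Nitrogen proportion of living biomass, g N per g.
#' @return g N m-2 day-1.
#' @export
n_in_biomass_from_solid_manure <- function(intake_living,
                                           prop_living_in_digestion,
                                           prop_n_living) {
  intake_living * prop_living_in_digestion * prop_n_living
}
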