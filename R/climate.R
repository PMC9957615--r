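#' Temperature limiting factor
#'
#' Trapezoidal response: 0 at or below `t_base` and at or above `t_max`, 1 on
#' the optimal plateau `[t_opt_lo, t_opt_hi]`, linear ramps between.
#'
#' @param tmean Daily mean air temperature, degC (vectorized).
#' @param t_base,t_opt_lo,t_opt_hi,t_max Cardinal temperatures, degC, with
#'   `t_base < t_opt_lo <= t_opt_hi < t_max`.
#' @return Factor in \[0, 1\].
#' @export
temperature_factor <- function(tmean, t_base, t_opt_lo, t_opt_hi, t_max) {
  up <- (tmean - t_base) / (t_opt_lo - t_base)
  down <- (t_max - tmean) / (t_max - t_opt_hi)
  pmin(1, pmax(0, pmin(up, down)))
}

#' Potential evapotranspiration
#'
#' Radiation-and-temperature driven estimate (Oudin-style):
#' `pet = rg / 2.45 * max(0, tmean + 5) / 100` mm/day, with `rg` in
#' MJ m-2 day-1 and 2.45 MJ kg-1 the latent heat of vaporization.
#'
#' @param rg Incident solar radiation, MJ m-2 day-1.
#' @param tmean Daily mean temperature, degC.
#' @return PET in mm/day.
#' @export
potential_evapotranspiration <- function(rg, tmean) {
  rg / 2.45 * pmax(0, tmean + 5) / 100
}

#' Daily soil water bucket step
#'
#' Single-bucket plant-available water balance. Actual evapotranspiration is
#' demand (`pet`) scaled by the moisture limiting factor evaluated on the
#' pre-step state, capped so the bucket cannot go negative; water above the
#' holding capacity drains. The balance closes exactly:
#' `precip = delta_water + aet + drainage`.
#'
#' @param water Stored plant-available water, mm (0 <= water <= whc).
#' @param whc Water-holding capacity, mm.
#' @param precip Precipitation, mm/day.
#' @param pet Potential evapotranspiration, mm/day.
#' @param w_crit Fraction of `whc` below which moisture limits (see
#'   [moisture_factor()]).
#' @return A list with `water` (next-day storage), `aet`, `drainage`, `fh`
#'   (the factor used), all vectorized.
#' @export
soil_water_step <- function(water, whc, precip, pet, w_crit) {
  fh <- moisture_factor(water, whc, w_crit)
  aet <- pmin(pet * fh, water + precip)
  w1 <- water + precip - aet
  drainage <- pmax(0, w1 - whc)
  list(water = w1 - drainage, aet = aet, drainage = drainage, fh = fh)
}

#' Moisture limiting factor
#'
#' Linear below the critical fill fraction, saturating at 1:
#' `FH = min(1, (water/whc) / w_crit)`.
#'
#' @inheritParams soil_water_step
#' @return Factor in \[0, 1\].
#' @export
moisture_factor <- function(water, whc, w_crit) {
  pmin(1, pmax(0, (water / whc) / w_crit))
}

#' Solar radiation over vegetation
#'
#' The understory conditional: where the main vegetation code equals the
#' overstory code there is no overstory and the full incident radiation
#' reaches the vegetation; otherwise only a fixed fraction (default 0.2)
#' penetrates the overstory canopy.
#'
#' @param rg Incident solar radiation (any non-negative quantity; the rule is
#'   homogeneous of degree 1).
#' @param com Main vegetation code.
#' @param com2 Overstory vegetation code (equal to `com` when absent).
#' @param understory_factor Fraction of radiation penetrating an overstory.
#' @return Radiation reaching the (under)story vegetation.
#' @export
radiation_over_vegetation <- function(rg, com, com2, understory_factor = 0.2) {
  ifelse(com == com2, rg, understory_factor * rg)
}

#' Radiation limiting factor
#'
#' Saturating (Michaelis-Menten) light response:
#' `FR = rg2 / (rg2 + rg_half)`, monotone increasing, 0.5 at `rg_half`.
#'
#' @param rg2 Radiation over the vegetation, MJ m-2 day-1.
#' @param rg_half Half-saturation radiation, MJ m-2 day-1 (> 0).
#' @return Factor in \[0, 1\] (attains 1 only in the saturating limit).
#' @export
radiation_factor <- function(rg2, rg_half) {
  ifelse(is.infinite(rg2), 1, rg2 / (rg2 + rg_half))
}

#' Phenology activity
#'
#' Reads the day-of-year activity (fraction of maximal physiological
#' activity) from a per-vegetation-type calendar.
#'
#' @param day_of_year Integer in 1..366.
#' @param calendar Numeric vector of length 366 with values in \[0, 1\].
#' @return Activity `ph` in \[0, 1\].
#' @export
phenology_activity <- function(day_of_year, calendar) {
  if (any(day_of_year < 1 | day_of_year > 366)) {
    pal_input_error("day_of_year must be within 1..366")
  }
  stopifnot(length(calendar) == 366)
  calendar[day_of_year]
}

#' Build a phenology calendar
#'
#' Trapezoidal growing-season activity: zero outside
#' `[season_start - ramp, season_end + ramp]`, one on
#' `[season_start, season_end]`, linear ramps of `ramp_days` on either side.
#'
#' @param season_start,season_end Day-of-year bounds of full activity.
#' @param ramp_days Length of the linear ramps, days.
#' @return Numeric vector of length 366.
#' @export
phenology_calendar <- function(season_start, season_end, ramp_days = 20) {
  doy <- 1:366
  up <- (doy - (season_start - ramp_days)) / ramp_days
  down <- ((season_end + ramp_days) - doy) / ramp_days
  pmin(1, pmax(0, pmin(up, down)))
}

#' Combined abiotic limiting factor
#'
#' The product composition `FTRH = FT * FR * FH`: symmetric, monotone in each
#' argument, bounded by the most limiting factor. Nitrogen limitation is kept
#' separate and applied at actual growth.
#'
#' @param ft,fr,fh Temperature, radiation and moisture factors in \[0, 1\].
#' @return `FTRH` in \[0, 1\].
#' @export
combine_limiting <- function(ft, fr, fh) {
  ft * fr * fh
}
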