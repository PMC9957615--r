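test_that("temperature response matches hand-computed trapezoid values", {
  # t_base=5, t_opt_lo=15: halfway up the ramp at 10
  expect_equal(temperature_factor(10, 5, 15, 22, 35), 0.5)
  expect_equal(temperature_factor(15, 5, 15, 22, 35), 1)
  expect_equal(temperature_factor(5, 5, 15, 22, 35), 0)
  expect_equal(temperature_factor(35, 5, 15, 22, 35), 0)
  expect_equal(temperature_factor(22, 5, 15, 22, 35), 1)
  expect_equal(temperature_factor(28.5, 5, 15, 22, 35), 0.5)
})

test_that("temperature response is unimodal and bounded over a full sweep", {
  tm <- seq(-20, 50, by = 0.01)
  ft <- temperature_factor(tm, 3, 14, 21, 36)
  expect_true(all(ft >= 0 & ft <= 1))
  expect_true(all(diff(ft[tm <= 14]) >= -1e-12))
  expect_true(all(diff(ft[tm >= 21]) <= 1e-12))
  expect_equal(max(ft), 1)
  expect_equal(min(ft), 0)
})

test_that("the soil bucket closes its water balance exactly", {
  # stated examples
  s <- soil_water_step(water = 50, whc = 100, precip = 0, pet = 0, w_crit = 0.6)
  expect_equal(s$water, 50); expect_equal(s$drainage, 0)

  s <- soil_water_step(water = 100, whc = 100, precip = 10, pet = 0, w_crit = 0.6)
  expect_equal(s$drainage, 10); expect_equal(s$water, 100)

  s <- soil_water_step(water = 50, whc = 100, precip = 20, pet = 10, w_crit = 0.5)
  # water/whc = 0.5, w_crit = 0.5 -> FH = 1, aet = 10
  expect_equal(s$aet, 10); expect_equal(s$water, 60); expect_equal(s$drainage, 0)

  # property: precip = delta_water + aet + drainage over random states
  set.seed(5)
  for (k in 1:200) {
    whc <- runif(1, 50, 200)
    w0 <- runif(1, 0, whc)
    pr <- rexp(1, 1 / 5); pet <- runif(1, 0, 8)
    st <- soil_water_step(w0, whc, pr, pet, runif(1, 0.2, 1))
    expect_equal(pr, (st$water - w0) + st$aet + st$drainage, tolerance = 1e-12)
    expect_true(st$water >= 0 && st$water <= whc + 1e-12)
  }
})

test_that("moisture factor is the capped fill ratio", {
  expect_equal(moisture_factor(100, 100, 0.6), 1)
  expect_equal(moisture_factor(0, 100, 0.6), 0)
  expect_equal(moisture_factor(30, 100, 0.6), 0.5)
  w <- seq(0, 100, by = 0.5)
  fh <- moisture_factor(w, 100, 0.7)
  expect_true(all(fh >= 0 & fh <= 1))
  expect_true(all(diff(fh) >= 0))
})

test_that("the understory conditional passes rg or a fifth of it", {
  expect_equal(radiation_over_vegetation(1, 7, 7), 1)
  expect_equal(radiation_over_vegetation(1, 7, 9), 0.2)
  expect_equal(radiation_over_vegetation(0, 7, 9), 0)
  expect_equal(radiation_over_vegetation(0, 3, 3), 0)
  # homogeneous of degree 1 in rg
  rg <- runif(50, 0, 35)
  expect_equal(radiation_over_vegetation(3 * rg, 1, 2),
               3 * radiation_over_vegetation(rg, 1, 2))
  expect_equal(radiation_over_vegetation(3 * rg, 2, 2),
               3 * radiation_over_vegetation(rg, 2, 2))
})

test_that("radiation factor saturates monotonically from zero", {
  expect_equal(radiation_factor(0, 8), 0)
  expect_equal(radiation_factor(8, 8), 0.5)
  rg <- seq(0, 35, by = 0.1)
  fr <- radiation_factor(rg, 7)
  expect_true(all(fr >= 0 & fr < 1))
  expect_true(all(diff(fr) > 0))
  expect_equal(radiation_factor(Inf, 7), 1)
})

test_that("phenology reads and interpolates the activity calendar", {
  cal <- rep(0, 366)
  expect_equal(phenology_activity(15, cal), 0)
  cal2 <- rep(1, 366)
  expect_equal(phenology_activity(200, cal2), 1)
  # a 10-day linear ramp built by the calendar helper: halfway at day 5 of it
  cal3 <- phenology_calendar(season_start = 110, season_end = 250, ramp_days = 10)
  expect_equal(cal3[105], 0.5)
  expect_equal(cal3[100], 0)
  expect_equal(cal3[110], 1)
  expect_error(phenology_activity(0, cal), class = "pal_input_error")
  expect_error(phenology_activity(367, cal), class = "pal_input_error")
})

test_that("the combined factor is the bounded, symmetric, monotone product", {
  expect_equal(combine_limiting(1, 1, 1), 1)
  expect_equal(combine_limiting(0, 0.9, 0.9), 0)
  # product of the tabulated FT, FR, FH example values
  expect_equal(combine_limiting(0.701909, 0.164, 1), 0.11511308, tolerance = 1e-6)
  set.seed(6)
  x <- runif(100); y <- runif(100); z <- runif(100)
  f <- combine_limiting(x, y, z)
  expect_true(all(f >= 0 & f <= 1))
  expect_true(all(f <= pmin(x, pmin(y, z)) + 1e-15))
  expect_equal(f, combine_limiting(z, x, y))       # symmetric
  expect_true(all(combine_limiting(pmin(x + 0.1, 1), y, z) >= f))  # monotone
})

test_that("every limiting factor stays within [0, 1] over exhaustive sweeps", {
  ft <- temperature_factor(seq(-20, 50, by = 0.05), 3, 14, 21, 36)
  fh <- moisture_factor(seq(0, 120, by = 0.25), 120, 0.6)
  fr <- radiation_factor(c(seq(0, 35, by = 0.05), Inf), 7)
  sweep <- expand.grid(growth = seq(0, 6, by = 0.25),
                       soil_n = seq(0, 12, by = 0.5))
  fn <- plant_uptake(sweep$growth, 0.025, sweep$soil_n)$fn
  for (f in list(ft, fh, fr, fn)) {
    expect_true(all(f >= 0 & f <= 1))
    expect_equal(min(f), 0)
    expect_equal(max(f), 1)
  }
})
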