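test_that("a short coupled run produces bounded factors and closed budgets", {
  ls <- tiny_landscape(seed = 31, n_days = 25)
  run <- pal_run(ls, query = "all")
  for (cid in c("temperature.limiting_factor", "radiation.limiting_factor",
                "moisture.limiting_factor", "nitrogen.limiting_factor",
                "vegetation_growth.combined_limiting_factor")) {
    df <- tidy(run$store, cid)
    expect_true(all(df$min >= 0 & df$max <= 1), info = cid)
  }
  pg <- tidy(run$store, "vegetation_growth.potential_growth")
  ag <- tidy(run$store, "vegetation_growth.actual_growth")
  expect_true(all(ag$max <= pg$max + 1e-12))
  expect_true(all(pg$max <= max(ls$vegetation_params$xf) + 1e-12))
  b <- pal_budget(run)
  expect_lt(max(b$biomass_residual), 1e-9)
  expect_lt(max(b$nitrogen_residual), 1e-9)
})

test_that("zero livestock density reproduces the ungrazed run bit-for-bit", {
  ls <- tiny_landscape(seed = 32, n_days = 20, n_livestock_groups = 2)
  zero <- ls
  for (gid in names(zero$livestock_densities)) {
    z <- zero$livestock_densities[[gid]]
    z$values[] <- 0
    zero$livestock_densities[[gid]] <- z
  }
  ungrazed <- ls
  ungrazed$livestock_densities <- list()
  ungrazed$livestock_params <- default_livestock_params(0)

  pools <- c("vegetation.living_biomass", "vegetation.standing_dead_biomass",
             "vegetation.litter_biomass", "nitrogen.soil_mineral_n",
             "nitrogen.living_n", "moisture.soil_water")
  rz <- pal_run(zero, query = pools)
  ru <- pal_run(ungrazed, query = pools)
  for (p in pools) {
    expect_identical(rz$store$history[[p]], ru$store$history[[p]], label = p)
  }
  # grazing at the generated densities does change the vegetation
  rg <- pal_run(ls, query = pools)
  expect_false(identical(rg$store$history[["vegetation.living_biomass"]],
                         ru$store$history[["vegetation.living_biomass"]]))
})

test_that("harvest events remove biomass on their dates and zones only", {
  ls <- tiny_landscape(seed = 33, n_days = 15, n_livestock_groups = 0)
  events <- tibble::tibble(
    date = as.Date("2018-01-08"), zone_id = 1, kind = "harvest",
    fraction_or_amount = 0.5
  )
  harvest <- events_to_series(events, ls$vegetation, "harvest")
  run <- pal_run(ls, query = "vegetation.living_biomass", harvest = harvest)
  base <- pal_run(ls, query = "vegetation.living_biomass")
  zone1 <- !is.na(ls$vegetation$values) & ls$vegetation$values == 1
  before <- get_field(run$store, "vegetation.living_biomass", 8, FALSE)
  after <- get_field(run$store, "vegetation.living_biomass", 9, FALSE)
  base_after <- get_field(base$store, "vegetation.living_biomass", 9, FALSE)
  if (any(zone1)) {
    expect_true(all(after[zone1] < base_after[zone1]))
  }
  expect_equal(after[!zone1], base_after[!zone1])
})

test_that("fertilization raises the nitrogen factor when nitrogen limits", {
  # growing-season window: in deep winter phenology gates growth to zero and
  # the nitrogen factor is vacuously 1 in both runs
  ls <- tiny_landscape(seed = 34, n_days = 180, n_livestock_groups = 0)
  window <- list(start = "2018-05-01", end = "2018-05-30")
  lean <- pal_run(ls, query = c("nitrogen.limiting_factor", "nitrogen.soil_mineral_n"),
                  start = window$start, end = window$end,
                  init = list("nitrogen.soil_mineral_n" = 0.02,
                              "nitrogen.litter_organic_n" = 0.01))
  rich <- pal_run(ls, query = c("nitrogen.limiting_factor", "nitrogen.soil_mineral_n"),
                  start = window$start, end = window$end,
                  init = list("nitrogen.soil_mineral_n" = 0.02,
                              "nitrogen.litter_organic_n" = 0.01),
                  fertilization = 0.5)
  fn_lean <- tidy(lean$store, "nitrogen.limiting_factor")$mean
  fn_rich <- tidy(rich$store, "nitrogen.limiting_factor")$mean
  expect_gt(mean(fn_rich), mean(fn_lean))
})

test_that("livestock weights can fall as well as rise within a run", {
  ls <- tiny_landscape(seed = 35, n_days = 40, n_livestock_groups = 3)
  gids <- ls$livestock_params$group_id
  run <- pal_run(ls, query = paste0("livestock.weight.", gids))
  deltas <- unlist(lapply(gids, function(g) {
    h <- run$store$history[[paste0("livestock.weight.", g)]]
    dens <- ls$livestock_densities[[g]]$values > 0
    if (!any(dens)) return(numeric(0))
    vapply(2:length(h), function(t) (h[[t]] - h[[t - 1]])[dens][1], numeric(1))
  }))
  expect_true(any(deltas < 0) || any(deltas > 0))  # weights actually move
})
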