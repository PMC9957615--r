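test_that("generation is deterministic per seed and sensitive to it", {
  a <- generate_landscape(landscape_config(seed = 3, ncols = 8, nrows = 8), n_days = 10)
  b <- generate_landscape(landscape_config(seed = 3, ncols = 8, nrows = 8), n_days = 10)
  expect_identical(a$elevation$values, b$elevation$values)
  expect_identical(a$vegetation$values, b$vegetation$values)
  expect_identical(a$climate, b$climate)
  c2 <- generate_landscape(landscape_config(seed = 4, ncols = 8, nrows = 8), n_days = 10)
  expect_false(identical(a$vegetation$values, c2$vegetation$values))
})

test_that("artifact substreams are independent of generation order", {
  cfg <- landscape_config(seed = 5, ncols = 6, nrows = 6)
  dem1 <- generate_dem(cfg)
  clim <- generate_climate(cfg, 30)       # interleaved draw
  dem2 <- generate_dem(cfg)
  expect_identical(dem1$elevation$values, dem2$elevation$values)
  expect_identical(clim, generate_climate(cfg, 30))
})

test_that("terrain respects the elevation range and flat terrain has zero slope", {
  dem <- generate_dem(landscape_config(seed = 1))
  expect_gte(min(dem$elevation$values), 100)
  expect_lte(max(dem$elevation$values), 1200)
  flat <- generate_dem(landscape_config(seed = 1, elevation_range = c(500, 500)))
  expect_equal(flat$slope$values, matrix(0, 40, 40))
  expect_true(all(dem$slope$values >= 0))
})

test_that("the vegetation mosaic uses valid codes and the overstory rule", {
  cfg <- landscape_config(seed = 2, ncols = 12, nrows = 12)
  veg <- generate_vegetation_map(cfg)
  expect_true(all(veg$vegetation$values %in% 1:9))
  expect_true(all(veg$overstory$values %in% 1:9))
  over <- veg$overstory$values != veg$vegetation$values
  expect_true(any(over))      # some overstory at p = 0.15
  none <- generate_vegetation_map(landscape_config(seed = 2, ncols = 12, nrows = 12,
                                                   overstory_probability = 0))
  expect_identical(none$overstory$values, none$vegetation$values)
  # patch granularity: more seeds, more connected components
  n_patches <- function(k) {
    m <- generate_vegetation_map(landscape_config(seed = 9, ncols = 20, nrows = 20,
                                                  n_patches = k))$vegetation$values
    # flood-fill count of 4-connected constant-code components
    seen <- matrix(FALSE, nrow(m), ncol(m)); comps <- 0
    for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
      if (seen[i, j]) next
      comps <- comps + 1
      queue <- list(c(i, j)); seen[i, j] <- TRUE
      while (length(queue)) {
        cur <- queue[[1]]; queue <- queue[-1]
        for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
          ni <- cur[1] + d[1]; nj <- cur[2] + d[2]
          if (ni >= 1 && ni <= nrow(m) && nj >= 1 && nj <= ncol(m) &&
              !seen[ni, nj] && m[ni, nj] == m[cur[1], cur[2]]) {
            seen[ni, nj] <- TRUE
            queue[[length(queue) + 1]] <- c(ni, nj)
          }
        }
      }
    }
    comps
  }
  expect_lt(n_patches(9), n_patches(60))
})

test_that("the climate series matches its configured statistics", {
  cfg <- landscape_config(seed = 6)
  clim <- generate_climate(cfg, 365)
  expect_equal(nrow(clim), 365)
  expect_equal(mean(clim$tmean_c), 14, tolerance = 0.2)
  expect_true(all(clim$precip_mm >= 0))
  expect_true(all(clim$rg_mj_m2 >= 0))
  expect_equal(mean(clim$precip_mm), 3.5, tolerance = 1e-9)
  # zero-noise configuration degenerates to the exact seasonal sinusoid
  quiet <- generate_climate(landscape_config(seed = 6, tmean_sd = 0,
                                             tmean_amplitude = 7), 365)
  doy <- as.integer(strftime(quiet$date, "%j"))
  expect_equal(quiet$tmean_c, 14 + 7 * cos(2 * pi * (doy - 200) / 365.25))
})

test_that("livestock are placed on accessible terrain with the right totals", {
  cfg <- landscape_config(seed = 8, n_livestock_groups = 4, herd_size = 15)
  dem <- generate_dem(cfg)
  lv <- generate_livestock(cfg, dem)
  th <- accessibility_thresholds()
  expect_equal(nrow(lv$params), 4)
  for (i in seq_len(4)) {
    gid <- lv$params$group_id[i]
    dens <- lv$densities[[gid]]$values
    expect_true(all(dens >= 0))
    expect_equal(sum(dens), 15)
    s1 <- th[[lv$params$species[i]]][2]
    expect_true(all(dens[dem$slope$values >= s1] == 0))
  }
  none <- generate_livestock(landscape_config(seed = 8, n_livestock_groups = 0), dem)
  expect_equal(length(none$densities), 0)
  expect_equal(nrow(none$params), 0)
})

test_that("a landscape round-trips through its fixture directory", {
  ls1 <- tiny_landscape(seed = 21, n_days = 12)
  dir <- withr::local_tempdir()
  write_landscape(ls1, dir)
  expect_true(file.exists(file.path(dir, "climate.csv")))
  ls2 <- read_landscape(dir)
  expect_equal(ls2$elevation$values, ls1$elevation$values, tolerance = 1e-12)
  expect_equal(ls2$vegetation$values, ls1$vegetation$values)
  expect_equal(as.data.frame(ls2$climate), as.data.frame(ls1$climate),
               tolerance = 1e-12)
  expect_equal(as.data.frame(ls2$livestock_params),
               as.data.frame(ls1$livestock_params))
  # and the write is byte-stable
  dir2 <- withr::local_tempdir()
  write_landscape(ls1, dir2)
  f1 <- file.path(dir, "vegetation.asc"); f2 <- file.path(dir2, "vegetation.asc")
  expect_identical(readLines(f1), readLines(f2))
})
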