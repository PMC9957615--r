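test_that("resampling is a no-op on the target grid and preserves constants", {
  g <- grid_spec(4, 4, cell_size = 50)
  f <- raster_field(matrix(runif(16), 4, 4), g, "x")
  expect_identical(resample_field(f, g)$values, f$values)

  coarse <- grid_spec(2, 2, cell_size = 100)
  const <- raster_field(matrix(7.5, 4, 4), g)
  expect_equal(resample_field(const, coarse)$values, matrix(7.5, 2, 2))
})

test_that("2x2 cells aggregate to their area-weighted mean", {
  g <- grid_spec(2, 2, cell_size = 50)
  f <- raster_field(matrix(c(1, 3, 2, 4), 2, 2), g)  # values {1,2,3,4}
  coarse <- grid_spec(1, 1, cell_size = 100)
  expect_equal(resample_field(f, coarse)$values[1, 1], 2.5)
})

test_that("resampling conserves the spatial mean under complete coverage", {
  set.seed(11)
  g <- grid_spec(12, 8, cell_size = 25)
  f <- raster_field(matrix(rnorm(96), 8, 12), g)
  coarse <- grid_spec(6, 4, cell_size = 50)
  r <- resample_field(f, coarse)
  expect_equal(mean(r$values), mean(f$values), tolerance = 1e-6)
})

test_that("categorical resampling never invents codes and uses nearest neighbour", {
  set.seed(12)
  g <- grid_spec(10, 10, cell_size = 10)
  codes <- matrix(sample(c(2L, 5L, 9L), 100, TRUE), 10, 10)
  f <- raster_field(codes, g, kind = "categorical")
  for (tg in list(grid_spec(5, 5, cell_size = 20), grid_spec(20, 20, cell_size = 5))) {
    r <- resample_field(f, tg)
    expect_true(all(r$values %in% c(2, 5, 9)))
  }
  # upsampling replicates the parent cell
  fine <- resample_field(f, grid_spec(20, 20, cell_size = 5))
  expect_equal(fine$values[1, 1], codes[1, 1])
  expect_equal(fine$values[2, 2], codes[1, 1])
})

test_that("nodata propagates when source coverage is below one half", {
  g <- grid_spec(2, 2, cell_size = 50)
  v <- matrix(c(1, NA, NA, NA), 2, 2)      # one valid cell = 25% coverage
  f <- raster_field(v, g)
  coarse <- grid_spec(1, 1, cell_size = 100)
  expect_true(is.na(resample_field(f, coarse)$values[1, 1]))
  v2 <- matrix(c(1, 3, NA, NA), 2, 2)      # 50% coverage passes
  expect_equal(resample_field(raster_field(v2, g), coarse)$values[1, 1], 2)
})

test_that("disjoint extents raise a resolution error naming both extents", {
  g <- grid_spec(2, 2, cell_size = 50, origin_x = 0)
  far <- grid_spec(2, 2, cell_size = 50, origin_x = 1e6)
  err <- expect_error(resample_field(raster_field(1, g), far),
                      class = "pal_resolution_error")
  expect_match(conditionMessage(err), "disjoint")
  expect_match(conditionMessage(err), "1e\\+06|1000000")
})

test_that("zonal statistics summarise per zone and ignore nodata", {
  g <- grid_spec(2, 2, cell_size = 50)
  field <- raster_field(matrix(c(1, 5, 3, 5), 2, 2), g)
  zones <- raster_field(matrix(c(1, 2, 1, 2), 2, 2), g, kind = "categorical")
  st <- zonal_statistics(field, zones)
  expect_equal(st$zone_id, c(1L, 2L))
  expect_equal(st$mean, c(2, 5))
  expect_equal(st$sum, c(4, 10))

  uni <- zonal_statistics(raster_field(2, g), raster_field(1, g, kind = "categorical"))
  expect_equal(uni$mean, 2)
  expect_equal(uni$sum, 2 * 4)

  empty <- zonal_statistics(raster_field(matrix(NA_real_, 2, 2), g),
                            raster_field(1, g, kind = "categorical"))
  expect_equal(nrow(empty), 0)

  other <- raster_field(1, grid_spec(3, 3), kind = "categorical")
  expect_error(zonal_statistics(field, other), class = "pal_resolution_error")
})

test_that("ASCII grid round-trips preserve values, grid and nodata", {
  g <- grid_spec(5, 4, cell_size = 50, origin_x = 100, origin_y = 900)
  v <- matrix(rnorm(20), 4, 5)
  v[2, 3] <- NA
  f <- raster_field(v, g, "x", "g/m2")
  path <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(f, path)
  back <- read_ascii_grid(path, "x", "g/m2")
  expect_equal(back$values, v, tolerance = 1e-12)
  expect_true(grid_equal(back$grid, g))
  expect_error(read_ascii_grid("/nonexistent/file.asc"), class = "pal_io_error")
})
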