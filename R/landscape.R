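#' Synthetic landscape configuration
#'
#' Seeded, fully reproducible generator settings for all model inputs:
#' terrain, vegetation map with optional overstory, daily climate series and
#' livestock distributions. Defaults emulate a temperate Atlantic mountain
#' pastureland: elevations between 100 and 1200 m, an annual mean temperature
#' of 14 degC, nine vegetation types, cattle and mare herds.
#'
#' @param seed Integer seed; every artifact derives its own substream from it
#'   so regenerating one artifact never changes another.
#' @param ncols,nrows,cell_size Grid settings (default 40 x 40 at 50 m).
#' @param n_vegetation_types Number of vegetation codes (default 9).
#' @param overstory_probability Per-cell probability of an overstory whose
#'   code differs from the main vegetation.
#' @param n_patches Granularity of the vegetation mosaic (Voronoi seeds).
#' @param elevation_range `c(min, max)` elevation in meters.
#' @param tmean_mean,tmean_amplitude Annual mean and seasonal amplitude of
#'   daily temperature, degC.
#' @param tmean_sd,precip_mean,wet_fraction,rg_mean,rg_amplitude,rg_sd
#'   Climate shape parameters: day-to-day temperature noise sd; mean
#'   precipitation (mm/day, all days); fraction of wet days; mean and
#'   seasonal amplitude and noise sd of solar radiation (MJ/m2/day).
#' @param n_livestock_groups Number of livestock groups (default 14).
#' @param herd_size Animals per group.
#' @param start_year First simulated year.
#' @return A `pal_landscape_config` list.
#' @export
landscape_config <- function(seed = 1L, ncols = 40, nrows = 40, cell_size = 50,
                             n_vegetation_types = 9,
                             overstory_probability = 0.15, n_patches = 25,
                             elevation_range = c(100, 1200),
                             tmean_mean = 14, tmean_amplitude = 7,
                             tmean_sd = 1.5,
                             precip_mean = 3.5, wet_fraction = 0.45,
                             rg_mean = 13, rg_amplitude = 8, rg_sd = 2,
                             n_livestock_groups = 14, herd_size = 20,
                             start_year = 2018) {
  stopifnot(n_vegetation_types >= 1, seed == as.integer(seed))
  structure(
    list(seed = as.integer(seed), ncols = ncols, nrows = nrows,
         cell_size = cell_size, n_vegetation_types = n_vegetation_types,
         overstory_probability = overstory_probability, n_patches = n_patches,
         elevation_range = elevation_range, tmean_mean = tmean_mean,
         tmean_amplitude = tmean_amplitude, tmean_sd = tmean_sd,
         precip_mean = precip_mean, wet_fraction = wet_fraction,
         rg_mean = rg_mean, rg_amplitude = rg_amplitude, rg_sd = rg_sd,
         n_livestock_groups = n_livestock_groups, herd_size = herd_size,
         start_year = start_year),
    class = "pal_landscape_config"
  )
}

# Named substream: each artifact draws from its own deterministic stream so
# generation order cannot couple outputs. Seeds stay below 2^31.
with_substream <- function(config, name, code) {
  offset <- sum(utf8ToInt(name)) %% 10000L
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed((config$seed %% 100000L) * 10000L + offset)
  force(code)
}

smooth_matrix <- function(m, passes = 3) {
  nr <- nrow(m); nc <- ncol(m)
  for (k in seq_len(passes)) {
    p <- m[c(1, 1:nr, nr), c(1, 1:nc, nc)]  # replicate-pad borders
    m <- (p[1:nr, 1:nc] + p[1:nr, 2:(nc + 1)] + p[1:nr, 3:(nc + 2)] +
          p[2:(nr + 1), 1:nc] + p[2:(nr + 1), 2:(nc + 1)] + p[2:(nr + 1), 3:(nc + 2)] +
          p[3:(nr + 2), 1:nc] + p[3:(nr + 2), 2:(nc + 1)] + p[3:(nr + 2), 3:(nc + 2)]) / 9
  }
  m
}

#' Generate terrain
#'
#' A smooth, spatially correlated elevation surface (low-frequency cosine
#' modes plus smoothed noise, rescaled into `elevation_range`) and its slope
#' in degrees by central differences.
#'
#' @param config A [landscape_config()].
#' @return List with `elevation` and `slope` (`pal_field`s).
#' @export
generate_dem <- function(config) {
  g <- grid_spec(config$ncols, config$nrows, config$cell_size)
  nr <- g$nrows; nc <- g$ncols
  elev <- with_substream(config, "dem", {
    row <- matrix(seq_len(nr) / nr, nr, nc)
    col <- matrix(rep(seq_len(nc) / nc, each = nr), nr, nc)
    base <- 0
    for (k in 1:4) {
      base <- base + stats::runif(1, 0.3, 1) *
        cos(2 * pi * (stats::runif(1, 0.5, 1.5) * row +
                      stats::runif(1, 0.5, 1.5) * col + stats::runif(1)))
    }
    base <- base + smooth_matrix(matrix(stats::rnorm(nr * nc, sd = 0.3), nr, nc), 4)
    lo <- config$elevation_range[1]; hi <- config$elevation_range[2]
    rng <- range(base)
    if (diff(rng) == 0 || lo == hi) {
      matrix(mean(c(lo, hi)), nr, nc)
    } else {
      lo + (base - rng[1]) / diff(rng) * (hi - lo)
    }
  })
  slope <- slope_from_elevation(elev, g$cell_size)
  list(
    elevation = raster_field(elev, g, "terrain.elevation", "m"),
    slope = raster_field(slope, g, "terrain.slope", "degree")
  )
}

#' @rdname generate_dem
#' @param elevation Elevation matrix (meters).
#' @param cell_size Cell size, meters.
#' @export
slope_from_elevation <- function(elevation, cell_size) {
  nr <- nrow(elevation); nc <- ncol(elevation)
  pad_r <- elevation[c(1, 1:nr, nr), ]
  pad_c <- elevation[, c(1, 1:nc, nc)]
  # central differences with replicated borders (border step is one cell)
  denom_r <- matrix(2, nr, nc); denom_r[c(1, nr), ] <- 1
  denom_c <- matrix(2, nr, nc); denom_c[, c(1, nc)] <- 1
  dz_dy <- (pad_r[3:(nr + 2), ] - pad_r[1:nr, ]) / (denom_r * cell_size)
  dz_dx <- (pad_c[, 3:(nc + 2)] - pad_c[, 1:nc]) / (denom_c * cell_size)
  atan(sqrt(dz_dx^2 + dz_dy^2)) * 180 / pi
}

#' Generate the vegetation mosaic
#'
#' Contiguous patches (Voronoi tessellation of seeded points) carrying codes
#' `1..n_vegetation_types`; an overstory code differing from the main code is
#' assigned in a seeded fraction of cells and equals the main code elsewhere.
#'
#' @param config A [landscape_config()].
#' @param dem Output of [generate_dem()] (unused by the default tessellation
#'   but accepted so callers can pass the terrain bundle through).
#' @return List with `vegetation` (main codes) and `overstory` (`pal_field`s,
#'   categorical).
#' @export
generate_vegetation_map <- function(config, dem = NULL) {
  g <- grid_spec(config$ncols, config$nrows, config$cell_size)
  nr <- g$nrows; nc <- g$ncols
  res <- with_substream(config, "vegetation", {
    k <- max(config$n_patches, config$n_vegetation_types)
    sr <- stats::runif(k, 1, nr)
    sc <- stats::runif(k, 1, nc)
    codes <- c(seq_len(config$n_vegetation_types),
               sample(config$n_vegetation_types, k - config$n_vegetation_types,
                      replace = TRUE))
    rows <- matrix(seq_len(nr), nr, nc)
    cols <- matrix(rep(seq_len(nc), each = nr), nr, nc)
    best <- matrix(Inf, nr, nc)
    com <- matrix(1, nr, nc)
    for (i in seq_len(k)) {
      d <- (rows - sr[i])^2 + (cols - sc[i])^2
      sel <- d < best
      best[sel] <- d[sel]
      com[sel] <- codes[i]
    }
    over <- com
    if (config$n_vegetation_types > 1 && config$overstory_probability > 0) {
      flip <- matrix(stats::runif(nr * nc) < config$overstory_probability, nr, nc)
      shift <- matrix(sample(config$n_vegetation_types - 1, nr * nc, replace = TRUE),
                      nr, nc)
      over[flip] <- ((com[flip] - 1 + shift[flip]) %% config$n_vegetation_types) + 1
    }
    list(com = com, over = over)
  })
  list(
    vegetation = raster_field(res$com, g, "vegetation.type", "code", "categorical"),
    overstory = raster_field(res$over, g, "vegetation.overstory_type", "code",
                             "categorical")
  )
}

#' Generate a daily climate series
#'
#' Sinusoidal seasonal cycles with seeded day-to-day noise: temperature
#' (annual mean `tmean_mean`, summer peak around day 200), precipitation
#' (wet days drawn at `wet_fraction`, exponential wet-day amounts with a
#' winter-leaning seasonal modulation, overall mean `precip_mean`) and solar
#' radiation (summer-peaking, floored at 0.1).
#'
#' @param config A [landscape_config()].
#' @param n_days Number of days (starting 1 January of `start_year`).
#' @return A tibble with `date`, `tmean_c`, `precip_mm`, `rg_mj_m2`.
#' @export
generate_climate <- function(config, n_days = 365) {
  stopifnot(n_days >= 1)
  dates <- seq(as.Date(sprintf("%d-01-01", config$start_year)),
               by = "day", length.out = n_days)
  doy <- as.integer(strftime(dates, "%j"))
  season <- cos(2 * pi * (doy - 200) / 365.25)
  with_substream(config, "climate", {
    tmean <- config$tmean_mean + config$tmean_amplitude * season +
      stats::rnorm(n_days, sd = config$tmean_sd)
    wet <- stats::runif(n_days) < config$wet_fraction
    wet_mod <- 1 - 0.4 * season   # wetter winters
    amount <- stats::rexp(n_days) * wet_mod
    precip <- ifelse(wet, amount, 0)
    if (mean(precip) > 0) precip <- precip * config$precip_mean / mean(precip)
    rg <- pmax(0.1, config$rg_mean + config$rg_amplitude * season +
                 stats::rnorm(n_days, sd = config$rg_sd))
    tibble::tibble(date = dates, tmean_c = tmean, precip_mm = precip,
                   rg_mj_m2 = rg)
  })
}

#' Generate livestock distributions
#'
#' Places each group's herd on contiguous low-slope cells (never on slopes at
#' or above the species' accessibility cutoff) and returns per-group density
#' rasters plus the group parameter table.
#'
#' @param config A [landscape_config()].
#' @param dem Output of [generate_dem()].
#' @return List with `densities` (named list of `pal_field`, animals per
#'   cell) and `params` (tibble, see [default_livestock_params()]).
#' @export
generate_livestock <- function(config, dem) {
  g <- dem$slope$grid
  nr <- g$nrows; nc <- g$ncols
  params <- default_livestock_params(config$n_livestock_groups, config$herd_size)
  th <- accessibility_thresholds()
  densities <- with_substream(config, "livestock", {
    out <- list()
    slope <- dem$slope$values
    for (i in seq_len(nrow(params))) {
      sp <- params$species[i]
      s1 <- th[[sp]][2]
      ok <- which(slope < s1)
      dens <- matrix(0, nr, nc)
      if (length(ok)) {
        centre <- sample(ok, 1)
        ci <- (centre - 1) %% nr + 1
        cj <- (centre - 1) %/% nr + 1
        rows <- matrix(seq_len(nr), nr, nc)
        cols <- matrix(rep(seq_len(nc), each = nr), nr, nc)
        d2 <- (rows - ci)^2 + (cols - cj)^2
        w <- exp(-d2 / (2 * (max(nr, nc) / 8)^2))
        w[slope >= s1] <- 0
        if (sum(w) > 0) {
          cells <- sample(length(w), params$herd_size[i], replace = TRUE,
                          prob = as.vector(w))
          for (cell in cells) dens[cell] <- dens[cell] + 1
        }
      }
      out[[params$group_id[i]]] <- raster_field(
        dens, g, paste0("livestock.density.", params$group_id[i]), "animal/cell"
      )
    }
    out
  })
  list(densities = densities, params = params)
}

#' Generate a complete synthetic landscape
#'
#' Bundles terrain, vegetation, climate, livestock and the parameter tables
#' into one reproducible object consumable by [pal_inputs()] / [pal_run()].
#'
#' @param config A [landscape_config()].
#' @param n_days Length of the climate series.
#' @return A `pal_landscape` list with elements `config`, `grid`,
#'   `elevation`, `slope`, `vegetation`, `overstory`, `climate`,
#'   `livestock_densities`, `livestock_params`, `vegetation_params`.
#' @export
generate_landscape <- function(config = landscape_config(), n_days = 365) {
  dem <- generate_dem(config)
  veg <- generate_vegetation_map(config, dem)
  clim <- generate_climate(config, n_days)
  lv <- generate_livestock(config, dem)
  structure(
    list(
      config = config, grid = dem$elevation$grid,
      elevation = dem$elevation, slope = dem$slope,
      vegetation = veg$vegetation, overstory = veg$overstory,
      climate = clim,
      livestock_densities = lv$densities, livestock_params = lv$params,
      vegetation_params = default_vegetation_params(config$n_vegetation_types)
    ),
    class = "pal_landscape"
  )
}

#' Write a landscape to a fixture directory
#'
#' Emits the exact input formats the simulator reads back: ASCII grids for
#' rasters, CSV for the climate series and parameter tables.
#'
#' @param landscape A `pal_landscape`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_landscape <- function(landscape, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) pal_io_error(sprintf("cannot create directory %s", dir))
  write_ascii_grid(landscape$elevation, file.path(dir, "elevation.asc"))
  write_ascii_grid(landscape$slope, file.path(dir, "slope.asc"))
  write_ascii_grid(landscape$vegetation, file.path(dir, "vegetation.asc"))
  write_ascii_grid(landscape$overstory, file.path(dir, "overstory.asc"))
  for (gid in names(landscape$livestock_densities)) {
    write_ascii_grid(landscape$livestock_densities[[gid]],
                     file.path(dir, paste0("density_", gid, ".asc")))
  }
  readr::write_csv(landscape$climate, file.path(dir, "climate.csv"))
  readr::write_csv(landscape$vegetation_params, file.path(dir, "vegetation_params.csv"))
  readr::write_csv(landscape$livestock_params, file.path(dir, "livestock_params.csv"))
  yaml::write_yaml(unclass(landscape$config), file.path(dir, "landscape_config.yaml"))
  invisible(dir)
}

#' Read a landscape back from a fixture directory
#'
#' @param dir Directory written by [write_landscape()].
#' @return A `pal_landscape`.
#' @export
read_landscape <- function(dir) {
  cfgf <- file.path(dir, "landscape_config.yaml")
  if (!file.exists(cfgf)) pal_io_error(sprintf("no landscape_config.yaml in %s", dir))
  config <- do.call(landscape_config, yaml::read_yaml(cfgf))
  lp <- readr::read_csv(file.path(dir, "livestock_params.csv"),
                        show_col_types = FALSE)
  densities <- list()
  for (gid in lp$group_id) {
    densities[[gid]] <- read_ascii_grid(
      file.path(dir, paste0("density_", gid, ".asc")),
      paste0("livestock.density.", gid), "animal/cell"
    )
  }
  structure(
    list(
      config = config,
      grid = read_ascii_grid(file.path(dir, "elevation.asc"))$grid,
      elevation = read_ascii_grid(file.path(dir, "elevation.asc"),
                                  "terrain.elevation", "m"),
      slope = read_ascii_grid(file.path(dir, "slope.asc"), "terrain.slope", "degree"),
      vegetation = read_ascii_grid(file.path(dir, "vegetation.asc"),
                                   "vegetation.type", "code", "categorical"),
      overstory = read_ascii_grid(file.path(dir, "overstory.asc"),
                                  "vegetation.overstory_type", "code", "categorical"),
      climate = readr::read_csv(file.path(dir, "climate.csv"), show_col_types = FALSE),
      livestock_densities = densities,
      livestock_params = lp,
      vegetation_params = readr::read_csv(file.path(dir, "vegetation_params.csv"),
                                          show_col_types = FALSE)
    ),
    class = "pal_landscape"
  )
}
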