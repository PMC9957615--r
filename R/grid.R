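#' Spatial grid specification
#'
#' A regular planar grid: row-major, origin at the top-left corner, 0-based
#' cell indices in the underlying geometry; cell (row i, col j) covers
#' `[origin_x + (j-1) cs, origin_x + j cs) x (origin_y - i cs, origin_y - (i-1) cs]`
#' with `cs = cell_size` in meters. A single planar reference is assumed
#' throughout; no projection handling is done.
#'
#' @param ncols,nrows Positive integer grid dimensions.
#' @param cell_size Cell edge length in meters (> 0).
#' @param origin_x,origin_y Coordinates of the top-left corner.
#' @param nodata Sentinel value written to files for missing cells.
#' @return An object of class `pal_grid`.
#' @export
grid_spec <- function(ncols, nrows, cell_size = 50, origin_x = 0,
                      origin_y = nrows * cell_size, nodata = -9999) {
  stopifnot(ncols >= 1, nrows >= 1, cell_size > 0)
  structure(
    list(
      ncols = as.integer(ncols), nrows = as.integer(nrows),
      cell_size = as.numeric(cell_size),
      origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
      nodata = nodata
    ),
    class = "pal_grid"
  )
}

grid_equal <- function(a, b) {
  a$ncols == b$ncols && a$nrows == b$nrows &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    isTRUE(all.equal(a$origin_x, b$origin_x)) &&
    isTRUE(all.equal(a$origin_y, b$origin_y))
}

grid_extent <- function(g) {
  c(
    xmin = g$origin_x, xmax = g$origin_x + g$ncols * g$cell_size,
    ymin = g$origin_y - g$nrows * g$cell_size, ymax = g$origin_y
  )
}

#' @export
print.pal_grid <- function(x, ...) {
  cat(sprintf(
    "<grid> %d x %d cells, %g m resolution, origin (%g, %g)\n",
    x$nrows, x$ncols, x$cell_size, x$origin_x, x$origin_y
  ))
  invisible(x)
}

#' Daily timeline
#'
#' A fixed daily-timestep timeline on the proleptic Gregorian calendar
#' (leap days included). Step `t = 1` is `start`.
#'
#' @param start,end Calendar dates (`Date` or ISO strings), `start <= end`.
#' @return An object of class `pal_timeline` with `n_steps = end - start + 1`.
#' @export
timeline <- function(start, end) {
  start <- as.Date(start)
  end <- as.Date(end)
  if (is.na(start) || is.na(end) || start > end) {
    pal_input_error("timeline requires valid dates with start <= end")
  }
  structure(
    list(
      start = start, end = end, step = "day",
      n_steps = as.integer(end - start) + 1L
    ),
    class = "pal_timeline"
  )
}

timeline_dates <- function(tl) seq(tl$start, tl$end, by = "day")

#' @export
print.pal_timeline <- function(x, ...) {
  cat(sprintf(
    "<timeline> %s .. %s, daily step, %d steps\n",
    format(x$start), format(x$end), x$n_steps
  ))
  invisible(x)
}

#' Simulation context
#'
#' A context is where and when a query is computed: a grid, a daily timeline
#' and a per-cell validity mask.
#'
#' @param grid A `pal_grid`.
#' @param timeline A `pal_timeline`.
#' @param mask Optional logical matrix (`nrows x ncols`); defaults to all
#'   valid. At least one valid cell is required.
#' @return An object of class `pal_context`.
#' @export
context <- function(grid, timeline, mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, grid$nrows, grid$ncols)
  stopifnot(is.logical(mask), nrow(mask) == grid$nrows, ncol(mask) == grid$ncols)
  if (!any(mask)) pal_input_error("context mask has no valid cell")
  structure(list(grid = grid, timeline = timeline, mask = mask),
            class = "pal_context")
}

#' Default simulation context
#'
#' The default context used when the caller does not specify one: 50 m cells,
#' daily timestep, 2018-01-01 through 2050-12-31 (12053 daily steps). The grid
#' dimensions are configurable because only the resolution and the timeline
#' are fixed defaults.
#'
#' @param ncols,nrows Grid dimensions (default 40 x 40).
#' @return A `pal_context`.
#' @examples
#' ctx <- make_default_context()
#' ctx$grid$cell_size       # 50
#' ctx$timeline$n_steps     # 12053
#' @export
make_default_context <- function(ncols = 40, nrows = 40) {
  context(
    grid_spec(ncols = ncols, nrows = nrows, cell_size = 50),
    timeline("2018-01-01", "2050-12-31")
  )
}

#' @export
print.pal_context <- function(x, ...) {
  print(x$grid)
  print(x$timeline)
  cat(sprintf("  %d valid cells\n", sum(x$mask)))
  invisible(x)
}
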