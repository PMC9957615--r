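#' Gridded quantities
#'
#' A raster field is the carrier for every per-cell quantity in the system: a
#' numeric matrix on a [grid_spec()] with a unit and a kind. Missing cells are
#' `NA` in memory and the grid's nodata sentinel on disk. Categorical fields
#' carry integer codes.
#'
#' @param values Numeric matrix, `grid$nrows x grid$ncols` (row 1 = top row),
#'   or a single number recycled to the grid.
#' @param grid A `pal_grid`.
#' @param concept_id Identifier of the concept the field observes.
#' @param units Unit name (see [unit_spec()]).
#' @param kind `"continuous"` or `"categorical"`.
#' @return An object of class `pal_field`.
#' @export
raster_field <- function(values, grid, concept_id = "", units = "1",
                         kind = c("continuous", "categorical")) {
  kind <- match.arg(kind)
  if (length(values) == 1L) values <- matrix(values, grid$nrows, grid$ncols)
  values <- as.matrix(values)
  if (nrow(values) != grid$nrows || ncol(values) != grid$ncols) {
    pal_input_error(sprintf(
      "field values are %d x %d but grid is %d x %d",
      nrow(values), ncol(values), grid$nrows, grid$ncols
    ))
  }
  if (kind == "categorical") {
    bad <- !is.na(values) & values != round(values)
    if (any(bad)) pal_input_error("categorical fields carry integer codes only")
    storage.mode(values) <- "double"
  }
  structure(
    list(concept_id = concept_id, grid = grid, units = units,
         values = values, kind = kind),
    class = "pal_field"
  )
}

#' @export
print.pal_field <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf(
    "<field> %s [%s, %s] on %d x %d grid; %s\n",
    if (nzchar(x$concept_id)) x$concept_id else "(unnamed)",
    x$units, x$kind, x$grid$nrows, x$grid$ncols,
    if (length(v)) sprintf("min %.4g / mean %.4g / max %.4g",
                           min(v), mean(v), max(v)) else "all nodata"
  ))
  invisible(x)
}

# Per-axis overlap of target intervals with source intervals.
# Returns for each target index a list of source indices and overlap lengths.
.axis_overlap <- function(src_lo, src_size, src_n, tgt_lo, tgt_size, tgt_n) {
  lapply(seq_len(tgt_n), function(k) {
    a <- tgt_lo + (k - 1) * tgt_size
    b <- a + tgt_size
    j0 <- floor((a - src_lo) / src_size) + 1
    j1 <- ceiling((b - src_lo) / src_size)
    j <- seq(max(1, j0), min(src_n, j1))
    if (!length(j) || max(1, j0) > min(src_n, j1)) {
      return(list(idx = integer(0), w = numeric(0)))
    }
    lo <- pmax(a, src_lo + (j - 1) * src_size)
    hi <- pmin(b, src_lo + j * src_size)
    keep <- hi > lo
    list(idx = j[keep], w = (hi - lo)[keep])
  })
}

#' Resample a field to a target grid
#'
#' Spatial mediation between grids of the same planar reference: continuous
#' fields are aggregated by area-weighted mean, categorical fields by nearest
#' neighbour (cell-centre lookup). A target cell becomes nodata when less than
#' half of its area is covered by valid source cells.
#'
#' @param field A `pal_field`.
#' @param target A `pal_grid` overlapping the field's grid.
#' @return A `pal_field` on `target`.
#' @export
resample_field <- function(field, target) {
  src <- field$grid
  if (grid_equal(src, target)) {
    out <- field
    out$grid <- target
    return(out)
  }
  es <- grid_extent(src)
  et <- grid_extent(target)
  if (es["xmax"] <= et["xmin"] || et["xmax"] <= es["xmin"] ||
      es["ymax"] <= et["ymin"] || et["ymax"] <= es["ymin"]) {
    pal_resolution_error(sprintf(
      "disjoint extents: source x[%g,%g] y[%g,%g] vs target x[%g,%g] y[%g,%g]",
      es["xmin"], es["xmax"], es["ymin"], es["ymax"],
      et["xmin"], et["xmax"], et["ymin"], et["ymax"]
    ))
  }
  out <- matrix(NA_real_, target$nrows, target$ncols)
  if (field$kind == "categorical") {
    # nearest neighbour at target cell centres
    cx <- target$origin_x + (seq_len(target$ncols) - 0.5) * target$cell_size
    cy <- target$origin_y - (seq_len(target$nrows) - 0.5) * target$cell_size
    jj <- floor((cx - src$origin_x) / src$cell_size) + 1
    ii <- floor((src$origin_y - cy) / src$cell_size) + 1
    okj <- jj >= 1 & jj <= src$ncols
    oki <- ii >= 1 & ii <= src$nrows
    for (i in which(oki)) {
      out[i, okj] <- field$values[ii[i], jj[okj]]
    }
  } else {
    # area-weighted mean; x axis increases with column, y decreases with row
    colw <- .axis_overlap(src$origin_x, src$cell_size, src$ncols,
                          target$origin_x, target$cell_size, target$ncols)
    # rows measured downward from the top edge
    roww <- .axis_overlap(0, src$cell_size, src$nrows,
                          src$origin_y - target$origin_y, target$cell_size,
                          target$nrows)
    area <- target$cell_size^2
    for (i in seq_len(target$nrows)) {
      ri <- roww[[i]]
      if (!length(ri$idx)) next
      for (j in seq_len(target$ncols)) {
        cj <- colw[[j]]
        if (!length(cj$idx)) next
        w <- outer(ri$w, cj$w)
        v <- field$values[ri$idx, cj$idx, drop = FALSE]
        ok <- !is.na(v)
        cov <- sum(w[ok]) / area
        if (cov >= 0.5 && cov > 0) {
          out[i, j] <- sum(w[ok] * v[ok]) / sum(w[ok])
        }
      }
    }
  }
  raster_field(out, target, concept_id = field$concept_id,
               units = field$units, kind = field$kind)
}

#' Zonal statistics
#'
#' Summarise a continuous field over the zones of a categorical field on the
#' same grid. Nodata cells (in either layer) are ignored.
#'
#' @param field A continuous `pal_field`.
#' @param zones A categorical `pal_field` on the same grid.
#' @return A tibble with columns `zone_id`, `mean`, `min`, `max`, `sum`,
#'   one row per zone code present; empty when no valid cell exists.
#' @export
zonal_statistics <- function(field, zones) {
  if (!grid_equal(field$grid, zones$grid)) {
    pal_resolution_error("zonal_statistics: field and zones are on different grids")
  }
  if (zones$kind != "categorical") {
    pal_input_error("zones must be a categorical field")
  }
  ok <- !is.na(field$values) & !is.na(zones$values)
  if (!any(ok)) {
    return(tibble::tibble(zone_id = integer(0), mean = numeric(0),
                          min = numeric(0), max = numeric(0), sum = numeric(0)))
  }
  tibble::tibble(zone_id = as.integer(zones$values[ok]), value = field$values[ok]) |>
    dplyr::group_by(.data$zone_id) |>
    dplyr::summarise(
      mean = mean(.data$value), min = min(.data$value),
      max = max(.data$value), sum = sum(.data$value), .groups = "drop"
    ) |>
    dplyr::arrange(.data$zone_id)
}

#' Read and write rasters as ESRI ASCII grids
#'
#' Plain-text raster exchange format used for all gridded inputs and outputs:
#' a six-line header (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`) followed by rows of numbers from the top row down.
#'
#' @param field A `pal_field` (`write_ascii_grid`).
#' @param path File path.
#' @param concept_id,units,kind Metadata attached to the field on read.
#' @return `read_ascii_grid()` returns a `pal_field`; `write_ascii_grid()`
#'   returns `path` invisibly.
#' @export
write_ascii_grid <- function(field, path) {
  g <- field$grid
  ext <- grid_extent(g)
  v <- field$values
  v[is.na(v)] <- g$nodata
  header <- c(
    sprintf("ncols %d", g$ncols),
    sprintf("nrows %d", g$nrows),
    sprintf("xllcorner %.10g", ext["xmin"]),
    sprintf("yllcorner %.10g", ext["ymin"]),
    sprintf("cellsize %.10g", g$cell_size),
    sprintf("NODATA_value %.10g", g$nodata)
  )
  rows <- apply(v, 1, function(r) paste(formatC(r, format = "g", digits = 15), collapse = " "))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path, concept_id = "", units = "1",
                            kind = c("continuous", "categorical")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) pal_io_error(sprintf("raster file not found: %s", path))
  lines <- readLines(path)
  hdr <- list()
  for (k in 1:6) {
    parts <- strsplit(trimws(lines[k]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  vals <- lapply(lines[-(1:6)], function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  m <- do.call(rbind, vals)
  if (nrow(m) != hdr$nrows || ncol(m) != hdr$ncols) {
    pal_io_error(sprintf("malformed ASCII grid: %s", path))
  }
  m[m == hdr$nodata_value] <- NA_real_
  g <- grid_spec(
    ncols = hdr$ncols, nrows = hdr$nrows, cell_size = hdr$cellsize,
    origin_x = hdr$xllcorner, origin_y = hdr$yllcorner + hdr$nrows * hdr$cellsize,
    nodata = hdr$nodata_value
  )
  raster_field(m, g, concept_id = concept_id, units = units, kind = kind)
}

#' @export
autoplot.pal_field <- function(object, ...) {
  g <- object$grid
  df <- tidyr::expand_grid(row = seq_len(g$nrows), col = seq_len(g$ncols))
  df$x <- g$origin_x + (df$col - 0.5) * g$cell_size
  df$y <- g$origin_y - (df$row - 0.5) * g$cell_size
  df$value <- as.vector(t(object$values))[(df$row - 1) * g$ncols + df$col]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = object$concept_id, fill = object$units,
      x = "x (m)", y = "y (m)"
    ) +
    ggplot2::scale_fill_viridis_c(na.value = "grey90")
}
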