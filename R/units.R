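#' Unit specifications and conversion
#'
#' The engine mediates units between data suppliers and consumers: every
#' concept declares a unit, and input fields expressed in a compatible unit of
#' the same dimension are converted on the fly. Only linear (scale-factor)
#' units are supported; the canonical unit of each dimension has scale 1.
#'
#' @details Supported dimensions and canonical units:
#' mass·area⁻¹ (g/m2), mass·area⁻¹·time⁻¹ (g/m2/day), temperature (degC),
#' length (m), length·time⁻¹ (mm/day is stored with scale relative to m/day),
#' energy·area⁻¹·time⁻¹ (MJ/m2/day), mass (g), time (day), angle (degree),
#' dimensionless (1).
#'
#' @param name Unit name, e.g. `"kg/ha"`.
#' @return `unit_spec()` returns an object of class `pal_unit` with fields
#'   `name`, `dimension` and `scale_to_canonical`.
#' @examples
#' convert_units(1, "kg/ha", "g/m2")   # 0.1
#' convert_units(1, "t/ha", "g/m2")    # 100
#' @export
unit_spec <- function(name) {
  if (inherits(name, "pal_unit")) return(name)
  row <- .pal_unit_table[[name]]
  if (is.null(row)) {
    pal_unit_error(sprintf("unknown unit '%s'", name))
  }
  structure(
    list(name = name, dimension = row$dimension, scale_to_canonical = row$scale),
    class = "pal_unit"
  )
}

.pal_unit_table <- local({
  u <- function(dimension, scale) list(dimension = dimension, scale = scale)
  list(
    "g/m2"      = u("mass/area", 1),
    "kg/m2"     = u("mass/area", 1000),
    "kg/ha"     = u("mass/area", 0.1),
    "t/ha"      = u("mass/area", 100),
    "gN/m2"     = u("mass/area", 1),
    "g/m2/day"  = u("mass/area/time", 1),
    "kg/ha/day" = u("mass/area/time", 0.1),
    "gN/m2/day" = u("mass/area/time", 1),
    "degC"      = u("temperature", 1),
    "m"         = u("length", 1),
    "cm"        = u("length", 0.01),
    "mm"        = u("length", 0.001),
    "km"        = u("length", 1000),
    "mm/day"    = u("length/time", 0.001),
    "m/day"     = u("length/time", 1),
    "MJ/m2/day" = u("energy/area/time", 1),
    "W/m2"      = u("energy/area/time", 0.0864),
    "g"         = u("mass", 1),
    "kg"        = u("mass", 1000),
    "t"         = u("mass", 1e6),
    "kg/day"    = u("mass/time", 1000),
    "g/day"     = u("mass/time", 1),
    "day"       = u("time", 1),
    "degree"    = u("angle", 1),
    "1"         = u("dimensionless", 1),
    "fraction"  = u("dimensionless", 1),
    "code"      = u("dimensionless", 1),
    "animal/cell" = u("dimensionless", 1)
  )
})

#' @rdname unit_spec
#' @param value Numeric value(s) to convert.
#' @param from,to Unit names or `pal_unit` objects of the same dimension.
#' @export
convert_units <- function(value, from, to) {
  from <- unit_spec(from)
  to <- unit_spec(to)
  if (from$dimension != to$dimension) {
    pal_unit_error(sprintf(
      "cannot convert between dimensions '%s' and '%s'",
      from$dimension, to$dimension
    ))
  }
  value * (from$scale_to_canonical / to$scale_to_canonical)
}

#' @export
print.pal_unit <- function(x, ...) {
  cat(sprintf("<unit> %s [%s], scale %g\n", x$name, x$dimension, x$scale_to_canonical))
  invisible(x)
}
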