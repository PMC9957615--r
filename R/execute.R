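#' Execute a resolved dataflow over a context
#'
#' Runs the dataflow's components in topological order for every timestep.
#' State concepts (those with an inserted change model) are initialized at the
#' first step — from an external input field or from their static component —
#' and then updated by explicit Euler with a one-day step:
#' `X(t+1) = X(t) + change_in_X(t)`. External inputs are mediated on the fly:
#' fields on a different grid are resampled to the context grid and values in
#' a different unit of the same dimension are converted to the concept's unit.
#'
#' @param dataflow A `pal_dataflow` from [resolve()].
#' @param context A `pal_context`.
#' @param inputs Named list keyed by external concept id. Each entry may be a
#'   `pal_field`, a matrix, a single number, a data frame with `date` and
#'   `value` columns (daily series, matched to the timeline), or a
#'   `function(t, context)` returning any of these.
#' @return A `pal_state_store`: per-concept, per-step field history plus the
#'   context and dataflow used.
#' @export
execute <- function(dataflow, context, inputs = list()) {
  stopifnot(inherits(dataflow, "pal_dataflow"), inherits(context, "pal_context"))
  n_steps <- context$timeline$n_steps
  grid <- context$grid
  mask <- context$mask
  registry <- dataflow$registry

  missing <- setdiff(dataflow$externals, names(inputs))
  if (length(missing)) {
    pal_execution_error(paste0(
      "missing external input(s): ", paste(sort(missing), collapse = ", ")
    ))
  }

  comp_nodes <- Filter(function(n) n$type == "component", dataflow$nodes)
  state <- dataflow$state_concepts
  is_series <- function(x) is.data.frame(x) || is.function(x)

  # A concept's value is step-invariant when it is a non-series external or
  # produced by a non-time-dependent component whose inputs are all static.
  # State concepts are never static. Static component outputs are computed
  # once and reused.
  static_concept <- stats::setNames(logical(0), character(0))
  for (e in dataflow$externals) {
    static_concept[[e]] <- !is_series(inputs[[e]]) && !(e %in% state)
  }
  for (nid in dataflow$order) {
    comp <- comp_nodes[[nid]]$component
    st <- !comp$time_dependent &&
      all(vapply(comp$inputs, function(c) isTRUE(static_concept[[c]]), logical(1)))
    static_concept[[comp$output]] <- st && !(comp$output %in% state)
  }

  coerce_input <- function(x, t, concept_id) {
    if (is.function(x)) x <- x(t, context)
    if (inherits(x, "pal_field")) {
      target_units <- registry_concept_units(registry, concept_id)
      if (!grid_equal(x$grid, grid)) x <- resample_field(x, grid)
      v <- x$values
      if (!identical(unit_spec(x$units)$name, unit_spec(target_units)$name)) {
        v <- convert_units(v, x$units, target_units)
      }
      return(v)
    }
    if (is.data.frame(x)) {
      d <- timeline_dates(context$timeline)[t]
      i <- match(d, as.Date(x$date))
      if (is.na(i)) {
        pal_execution_error(sprintf(
          "input series for '%s' has no value for %s (dynamic runs need data for every step)",
          concept_id, format(d)
        ))
      }
      return(matrix(x$value[i], grid$nrows, grid$ncols))
    }
    if (length(x) == 1L) return(matrix(as.numeric(x), grid$nrows, grid$ncols))
    x <- as.matrix(x)
    if (nrow(x) != grid$nrows || ncol(x) != grid$ncols) {
      pal_execution_error(sprintf("input '%s' has wrong dimensions", concept_id))
    }
    x
  }

  history <- stats::setNames(
    lapply(seq_along(dataflow$producer), function(i) vector("list", n_steps)),
    names(dataflow$producer)
  )
  static_cache <- list()
  state_values <- list()

  check_finite <- function(v, who, t) {
    bad <- !is.finite(v) & mask
    if (any(bad)) {
      ij <- which(bad, arr.ind = TRUE)[1, ]
      pal_numerical_error(sprintf(
        "non-finite value from '%s' at step %d, cell (%d,%d)", who, t, ij[1], ij[2]
      ))
    }
  }

  write_once <- function(concept_id, t, v) {
    if (!is.null(history[[concept_id]][[t]])) {
      pal_execution_error(sprintf(
        "field for '%s' at step %d written twice", concept_id, t
      ))
    }
    history[[concept_id]][[t]] <<- v
  }

  for (t in seq_len(n_steps)) {
    values <- list()

    # externals first (initialization inputs only read at step 1 for states)
    for (e in dataflow$externals) {
      if (e %in% state) {
        if (t == 1L) {
          v <- coerce_input(inputs[[e]], t, e)
          state_values[[e]] <- v
        }
        next
      }
      if (isTRUE(static_concept[[e]]) && !is.null(static_cache[[e]])) {
        values[[e]] <- static_cache[[e]]
      } else {
        values[[e]] <- coerce_input(inputs[[e]], t, e)
        if (isTRUE(static_concept[[e]])) static_cache[[e]] <- values[[e]]
      }
    }
    for (s in state) values[[s]] <- state_values[[s]]

    for (nid in dataflow$order) {
      comp <- comp_nodes[[nid]]$component
      out_id <- comp$output
      if (out_id %in% state && t > 1L) next  # state producers are init-only
      if (isTRUE(static_concept[[out_id]]) && !is.null(static_cache[[out_id]])) {
        values[[out_id]] <- static_cache[[out_id]]
        next
      }
      ins <- values[comp$inputs]
      if (any(vapply(ins, is.null, logical(1)))) {
        miss <- comp$inputs[vapply(ins, is.null, logical(1))]
        pal_execution_error(sprintf(
          "component '%s' read unwritten concept(s): %s",
          comp$id, paste(miss, collapse = ", ")
        ))
      }
      v <- comp$compute(ins, t, context)
      if (length(v) == 1L) v <- matrix(v, grid$nrows, grid$ncols)
      if (!is.matrix(v)) v <- matrix(v, grid$nrows, grid$ncols)
      check_finite(v, comp$id, t)
      values[[out_id]] <- v
      if (out_id %in% state) state_values[[out_id]] <- v
      if (isTRUE(static_concept[[out_id]])) static_cache[[out_id]] <- v
    }

    for (cid in names(values)) {
      if (cid %in% names(history)) write_once(cid, t, values[[cid]])
    }

    # Euler update of dynamic state for the next step; tiny negative rounding
    # residues from rescaled outflows are clamped to zero.
    if (t < n_steps) {
      for (s in state) {
        ch <- values[[dataflow$nodes[[dataflow$change_for[[s]]]]$component$output]]
        state_values[[s]] <- pmax(state_values[[s]] + ch, 0)
      }
    }
  }

  structure(
    list(history = history, context = context, dataflow = dataflow),
    class = "pal_state_store"
  )
}

#' Read a field from a state store
#'
#' @param store A `pal_state_store`.
#' @param concept_id Concept id present in the store.
#' @param t Timestep index (default: last step).
#' @param as_field Return a `pal_field` (default) or the bare matrix.
#' @return A `pal_field` or matrix.
#' @export
get_field <- function(store, concept_id, t = NULL, as_field = TRUE) {
  h <- store$history[[concept_id]]
  if (is.null(h)) {
    pal_execution_error(sprintf("concept '%s' is not in the store", concept_id))
  }
  if (is.null(t)) t <- store$context$timeline$n_steps
  v <- h[[t]]
  if (is.null(v)) {
    pal_execution_error(sprintf("concept '%s' has no field at step %d", concept_id, t))
  }
  if (!as_field) return(v)
  raster_field(
    v, store$context$grid, concept_id = concept_id,
    units = registry_concept_units(store$dataflow$registry, concept_id)
  )
}

#' @export
print.pal_state_store <- function(x, ...) {
  cat(sprintf(
    "<state store> %d concepts x %d steps on %d x %d grid\n",
    length(x$history), x$context$timeline$n_steps,
    x$context$grid$nrows, x$context$grid$ncols
  ))
  invisible(x)
}

#' @export
tidy.pal_state_store <- function(x, concepts = NULL, ...) {
  mask <- x$context$mask
  if (is.null(concepts)) concepts <- names(x$history)
  purrr::map_dfr(concepts, function(cid) {
    purrr::map_dfr(seq_along(x$history[[cid]]), function(t) {
      v <- x$history[[cid]][[t]]
      if (is.null(v)) return(NULL)
      vv <- v[mask & !is.na(v)]
      tibble::tibble(
        concept = cid, step = t,
        date = timeline_dates(x$context$timeline)[t],
        mean = mean(vv), min = min(vv), max = max(vv)
      )
    })
  })
}

#' @export
glance.pal_state_store <- function(x, ...) {
  tibble::tibble(
    n_concepts = length(x$history),
    n_steps = x$context$timeline$n_steps,
    n_cells = sum(x$context$mask)
  )
}

#' Plot stored concepts through time
#'
#' Spatial-mean trajectories of one or more concepts from a run.
#'
#' @param store A `pal_state_store`.
#' @param concepts Concept ids to plot.
#' @return A ggplot object.
#' @export
plot_timeseries <- function(store, concepts) {
  df <- tidy(store, concepts = concepts)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$date, y = .data$mean,
                                   colour = .data$concept)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = NULL, y = "spatial mean", colour = "concept")
}
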