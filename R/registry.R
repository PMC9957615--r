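#' Concepts and component models
#'
#' A concept is a named quantity ("what can be observed"); a component model
#' is a named computation producing exactly one concept from other concepts.
#' Dependencies between components are expressed purely as concept ids and are
#' resolved at query time, so components never reference each other directly.
#'
#' @param id Dotted identifier, e.g. `"radiation.limiting_factor"`.
#' @param description Free-text description.
#' @param units Unit name the concept is expressed in.
#' @param nature `"quality"`, `"amount"` or `"process-rate"`.
#' @return `concept()` returns a `pal_concept`.
#' @export
concept <- function(id, description = "", units = "1",
                    nature = c("quality", "amount", "process-rate")) {
  nature <- match.arg(nature)
  unit_spec(units)  # validate
  structure(list(id = id, description = description, units = units,
                 nature = nature),
            class = "pal_concept")
}

#' @rdname concept
#'
#' @param namespace One of the ten thematic namespaces (see
#'   [pal_namespaces()]), or any other tag for user components.
#' @param output A `pal_concept` (or id string) the component produces.
#' @param inputs List of `pal_concept`s or id strings consumed.
#' @param compute `function(inputs, t, context)` mapping a named list of
#'   per-cell matrices (one per input concept) and the timestep index to the
#'   output matrix. Must be pure: no hidden state.
#' @param is_change_model If `TRUE` the component produces the per-day change
#'   of the state concept `of_concept`; its output id must then follow the
#'   `<ns>.change_in_<name>` convention.
#' @param of_concept For change models, the id of the state concept changed.
#' @param provenance `"resource"`, `"table"` or `"expression"` (what kind of
#'   source the component embodies, mirrored into dataflow exports).
#' @param time_dependent Set `TRUE` when `compute` reads `t` (e.g. phenology),
#'   so its output is never cached across steps.
#' @param project Optional project tag used by the scoping rules.
#' @export
component_model <- function(id, namespace, output, inputs = list(), compute,
                            is_change_model = FALSE, of_concept = NULL,
                            provenance = c("expression", "table", "resource"),
                            time_dependent = FALSE, project = "pal",
                            description = "") {
  provenance <- match.arg(provenance)
  as_id <- function(x) if (inherits(x, "pal_concept")) x$id else as.character(x)
  output_id <- as_id(output)
  input_ids <- vapply(inputs, as_id, character(1))
  if (is_change_model) {
    if (is.null(of_concept)) {
      pal_registration_error("change models must name the concept they change (of_concept)")
    }
    leaf <- sub("^.*\\.", "", of_concept)
    expected <- paste0("change_in_", leaf)
    if (sub("^.*\\.", "", output_id) != expected) {
      pal_registration_error(sprintf(
        "change model output '%s' must be named '<namespace>.%s'", output_id, expected
      ))
    }
  }
  stopifnot(is.function(compute))
  structure(
    list(id = id, namespace = namespace, output = output_id,
         inputs = input_ids, compute = compute,
         is_change_model = is_change_model, of_concept = of_concept,
         provenance = provenance, time_dependent = time_dependent,
         project = project, description = description),
    class = "pal_component"
  )
}

#' The ten thematic namespaces
#'
#' @return Character vector of the namespace tags components are grouped in.
#' @export
pal_namespaces <- function() {
  c("moisture", "radiation", "temperature", "vegetation_growth",
    "senescence", "litterfall", "ingestion", "livestock_mass",
    "excretion", "nitrogen")
}

#' Model registry
#'
#' Holds components and declared external inputs. At most one component may
#' produce a given concept within a namespace; several namespaces may offer
#' components for the same concept, in which case the scoping rules
#' (same namespace > same project > global, ties broken lexicographically by
#' component id) pick one at resolution time.
#'
#' @return `model_registry()` returns an empty `pal_registry`.
#' @export
model_registry <- function() {
  structure(
    list(components = list(), concepts = list(), externals = character(0)),
    class = "pal_registry"
  )
}

#' @rdname model_registry
#' @param registry A `pal_registry`.
#' @param component A `pal_component`.
#' @export
register_component <- function(registry, component) {
  stopifnot(inherits(registry, "pal_registry"), inherits(component, "pal_component"))
  if (component$id %in% names(registry$components)) {
    pal_registration_error(sprintf("component id '%s' already registered", component$id))
  }
  dup <- Filter(function(c) c$output == component$output &&
                  c$namespace == component$namespace,
                registry$components)
  if (length(dup)) {
    pal_registration_error(sprintf(
      "a component for '%s' already exists in namespace '%s'",
      component$output, component$namespace
    ))
  }
  registry$components[[component$id]] <- component
  registry
}

#' @rdname model_registry
#' @param x A `pal_concept` (or id) declared as supplied from outside the
#'   registry (data, initialization values).
#' @export
declare_external <- function(registry, x) {
  id <- if (inherits(x, "pal_concept")) x$id else as.character(x)
  if (inherits(x, "pal_concept")) registry$concepts[[id]] <- x
  registry$externals <- union(registry$externals, id)
  registry
}

#' @rdname model_registry
#' @export
register_concept <- function(registry, x) {
  stopifnot(inherits(x, "pal_concept"))
  registry$concepts[[x$id]] <- x
  registry
}

registry_concept_units <- function(registry, id) {
  c <- registry$concepts[[id]]
  if (is.null(c)) "1" else c$units
}

# All components producing `concept_id`, ranked by the scoping rules relative
# to the consumer's (namespace, project). Deterministic.
lookup_components <- function(registry, concept_id, scope = list()) {
  cands <- Filter(function(c) c$output == concept_id && !c$is_change_model,
                  registry$components)
  if (!length(cands)) return(list())
  rank <- vapply(cands, function(c) {
    r <- 3L
    if (!is.null(scope$project) && identical(c$project, scope$project)) r <- 2L
    if (!is.null(scope$namespace) && identical(c$namespace, scope$namespace)) r <- 1L
    r
  }, integer(1))
  ids <- vapply(cands, `[[`, character(1), "id")
  cands[order(rank, ids)]
}

lookup_change_model <- function(registry, concept_id) {
  cands <- Filter(function(c) c$is_change_model && identical(c$of_concept, concept_id),
                  registry$components)
  if (!length(cands)) return(NULL)
  ids <- sort(vapply(cands, `[[`, character(1), "id"))
  cands[[which(vapply(cands, `[[`, character(1), "id") == ids[1])[1]]]
}

#' @export
print.pal_registry <- function(x, ...) {
  cat(sprintf("<registry> %d components, %d external inputs\n",
              length(x$components), length(x$externals)))
  ns <- sort(unique(vapply(x$components, `[[`, character(1), "namespace")))
  if (length(ns)) cat("  namespaces:", paste(ns, collapse = ", "), "\n")
  invisible(x)
}

#' List registered concepts
#'
#' @param registry A `pal_registry`.
#' @param filter Optional substring; only matching concept ids are returned.
#' @return A tibble with one row per concept produced by a component or
#'   declared external: `concept`, `namespace`, `units`, `kind`,
#'   `description`. Stable (alphabetical) order.
#' @export
pal_list_concepts <- function(registry, filter = NULL) {
  rows <- lapply(registry$components, function(c) {
    tibble::tibble(
      concept = c$output, namespace = c$namespace,
      units = registry_concept_units(registry, c$output),
      kind = if (c$is_change_model) "change" else "model",
      description = c$description
    )
  })
  ext <- lapply(registry$externals, function(id) {
    cc <- registry$concepts[[id]]
    tibble::tibble(
      concept = id, namespace = "(external)",
      units = registry_concept_units(registry, id), kind = "external",
      description = if (is.null(cc)) "" else cc$description
    )
  })
  out <- dplyr::bind_rows(c(rows, ext)) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$concept, .data$namespace)
  if (!is.null(filter) && nzchar(filter)) {
    out <- dplyr::filter(out, grepl(filter, .data$concept, fixed = TRUE))
  }
  out
}

#' Serialize a registry description to YAML
#'
#' Writes the structural part of the registry (ids, namespaces, outputs,
#' inputs, provenance) — not the compute closures — for inspection and
#' provenance archival.
#'
#' @param registry A `pal_registry`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_registry_yaml <- function(registry, path) {
  desc <- list(
    externals = as.list(sort(registry$externals)),
    components = lapply(
      registry$components[order(names(registry$components))],
      function(c) {
        list(id = c$id, namespace = c$namespace, output = c$output,
             inputs = as.list(c$inputs), change_model = c$is_change_model,
             provenance = c$provenance)
      }
    )
  )
  yaml::write_yaml(desc, path)
  invisible(path)
}
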