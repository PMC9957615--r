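#' Resolve a concept query into a dataflow
#'
#' Builds, at query time, the directed acyclic graph of component models that
#' answers one or more concept queries in a context. Candidate components are
#' ranked by the scoping rules (same namespace > same project > global, ties
#' broken lexicographically by id). On timelines longer than one step, any
#' resolved concept that has a registered change model becomes a dynamic state
#' variable: the change model and its own dependencies are inserted into the
#' dataflow automatically.
#'
#' @param query Concept id or vector of ids (the sinks of the dataflow).
#' @param registry A `pal_registry`.
#' @param context A `pal_context` (its timeline decides dynamization).
#' @return A `pal_dataflow`: nodes (components and external inputs), edges
#'   (concept-typed dependencies), a topological execution order, the set of
#'   state concepts, and per-node provenance.
#' @export
resolve <- function(query, registry, context) {
  stopifnot(inherits(registry, "pal_registry"), inherits(context, "pal_context"))
  dynamic <- context$timeline$n_steps > 1L

  nodes <- list()      # id -> list(id, type, component?, provenance)
  producer <- list()   # concept id -> node id producing its within-step value
  state_concepts <- character(0)
  change_for <- list() # state concept -> change component id

  resolve_concept <- function(concept_id, scope, chain) {
    if (is.null(producer[[concept_id]]) && concept_id %in% chain) {
      cyc <- c(chain[which(chain == concept_id):length(chain)], concept_id)
      pal_cycle_error(paste0("dependency cycle: ", paste(cyc, collapse = " -> ")))
    }
    if (!is.null(producer[[concept_id]])) {
      # already resolved; still ensure dynamization is considered below
    } else {

    if (concept_id %in% registry$externals) {
      nid <- paste0("external:", concept_id)
      nodes[[nid]] <<- list(id = nid, type = "external", concept = concept_id,
                            provenance = "resource")
      producer[[concept_id]] <<- nid
    } else {
      cands <- lookup_components(registry, concept_id, scope)
      if (!length(cands)) {
        pal_resolution_error(sprintf(
          "cannot resolve concept '%s' (chain: %s): no component and not external",
          concept_id,
          if (length(chain)) paste(chain, collapse = " -> ") else "(query)"
        ))
      }
      comp <- cands[[1]]
      nodes[[comp$id]] <<- list(id = comp$id, type = "component", component = comp,
                                concept = concept_id, provenance = comp$provenance)
      producer[[concept_id]] <<- comp$id
      for (dep in comp$inputs) {
        resolve_concept(dep, list(namespace = comp$namespace, project = comp$project),
                        c(chain, concept_id))
      }
    }
    }  # end unresolved branch

    if (dynamic && is.null(change_for[[concept_id]])) {
      cm <- lookup_change_model(registry, concept_id)
      if (!is.null(cm)) {
        state_concepts <<- union(state_concepts, concept_id)
        change_for[[concept_id]] <<- cm$id
        nodes[[cm$id]] <<- list(id = cm$id, type = "component", component = cm,
                                concept = cm$output, provenance = cm$provenance)
        producer[[cm$output]] <<- cm$id
        # the change model's result feeds the next step, so its dependency
        # chain starts fresh: reading the state it changes is not a cycle
        for (dep in cm$inputs) {
          resolve_concept(dep, list(namespace = cm$namespace, project = cm$project),
                          character(0))
        }
      }
    }
    invisible(NULL)
  }

  for (q in query) resolve_concept(q, list(), character(0))

  # Within-step dependency edges. A state concept's value at step t is known
  # at step start, so consumers of a state concept do not depend on its change
  # model within the step.
  edges <- list()
  for (n in nodes) {
    if (n$type != "component") next
    for (dep in n$component$inputs) {
      if (dep %in% state_concepts || dep %in% registry$externals) {
        src <- producer[[dep]]
        # externals/state: edge recorded for provenance but imposes no order
        edges[[length(edges) + 1L]] <- list(from = src, to = n$id, concept = dep,
                                            ordering = FALSE)
      } else {
        edges[[length(edges) + 1L]] <- list(from = producer[[dep]], to = n$id,
                                            concept = dep, ordering = TRUE)
      }
    }
  }

  order <- topo_order(nodes, edges)

  structure(
    list(query = query, nodes = nodes, edges = edges, order = order,
         state_concepts = state_concepts, change_for = change_for,
         producer = producer, externals = intersect(
           vapply(nodes, function(n) if (n$type == "external") n$concept else "",
                  character(1)), registry$externals),
         registry = registry),
    class = "pal_dataflow"
  )
}

# Kahn's algorithm over component nodes; deterministic (ready set kept sorted).
topo_order <- function(nodes, edges) {
  comp_ids <- names(Filter(function(n) n$type == "component", nodes))
  indeg <- stats::setNames(integer(length(comp_ids)), comp_ids)
  out <- stats::setNames(vector("list", length(comp_ids)), comp_ids)
  for (e in edges) {
    if (!isTRUE(e$ordering)) next
    if (e$from %in% comp_ids && e$to %in% comp_ids) {
      indeg[[e$to]] <- indeg[[e$to]] + 1L
      out[[e$from]] <- c(out[[e$from]], e$to)
    }
  }
  ready <- sort(names(indeg)[indeg == 0L])
  order <- character(0)
  while (length(ready)) {
    n <- ready[1]
    ready <- ready[-1]
    order <- c(order, n)
    for (m in out[[n]]) {
      indeg[[m]] <- indeg[[m]] - 1L
      if (indeg[[m]] == 0L) ready <- sort(c(ready, m))
    }
  }
  if (length(order) != length(comp_ids)) {
    leftover <- setdiff(comp_ids, order)
    pal_cycle_error(paste0(
      "dependency cycle among components: ", paste(sort(leftover), collapse = ", ")
    ))
  }
  order
}

#' @export
print.pal_dataflow <- function(x, ...) {
  ncomp <- sum(vapply(x$nodes, function(n) n$type == "component", logical(1)))
  cat(sprintf(
    "<dataflow> query %s: %d components, %d external inputs, %d state concepts\n",
    paste(x$query, collapse = ", "), ncomp, length(x$externals),
    length(x$state_concepts)
  ))
  invisible(x)
}

#' @export
tidy.pal_dataflow <- function(x, ...) {
  purrr::map_dfr(x$nodes, function(n) {
    tibble::tibble(
      node = n$id, type = n$type, concept = n$concept,
      namespace = if (n$type == "component") n$component$namespace else NA_character_,
      provenance = n$provenance,
      change_model = n$type == "component" && isTRUE(n$component$is_change_model)
    )
  }) |> dplyr::arrange(.data$node)
}

#' @export
glance.pal_dataflow <- function(x, ...) {
  tibble::tibble(
    n_components = sum(vapply(x$nodes, function(n) n$type == "component", logical(1))),
    n_externals = length(x$externals),
    n_edges = length(x$edges),
    n_state_concepts = length(x$state_concepts),
    n_namespaces = length(unique(stats::na.omit(tidy(x)$namespace)))
  )
}
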