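#' Build the producer/consumer coupling graph over an enzyme set
#'
#' Two enzymes are coupled when some non-currency compound is a product of a
#' reaction of one and a substrate of a reaction of the other (reversible
#' reactions contribute both sides to both roles). Coupling is kept
#' undirected — consecutive steps of a metabolic route may run in either
#' biosynthetic direction — with the linking compounds stored as edge
#' provenance.
#'
#' @param db a [pathway_db()].
#' @param enzyme_set character vector of EC ids, all present in `db`.
#' @param policy a [currency_policy()]; `NULL` for the default set.
#' @return A [crosstalk_network()] of type `"coupling"`.
#' @export
build_coupling_graph <- function(db, enzyme_set, policy = NULL) {
  stopifnot(inherits(db, "pathway_db"))
  policy <- check_policy(policy, db)
  enz <- enzymes_by_ec(db)
  unknown <- setdiff(enzyme_set, enz$ec)
  if (length(unknown)) stop("unknown enzyme id(s): ", paste(sort(unknown), collapse = ", "))
  ecs <- sort(unique(enzyme_set))
  idx <- ec_compound_index(db, ecs)
  cur <- policy$currency_ids
  nodes <- tibble::tibble(id = ecs, kind = "enzyme")
  edges <- list()
  if (length(ecs) >= 2L) {
    for (i in seq_len(length(ecs) - 1L)) {
      for (j in (i + 1L):length(ecs)) {
        link <- union(
          intersect(idx[[ecs[i]]]$products, idx[[ecs[j]]]$substrates),
          intersect(idx[[ecs[j]]]$products, idx[[ecs[i]]]$substrates))
        link <- setdiff(link, cur)
        if (length(link)) {
          edges[[length(edges) + 1L]] <- tibble::tibble(
            from = ecs[i], to = ecs[j], relation = "shares_compound",
            provenance = list(sort(link)))
        }
      }
    }
  }
  crosstalk_network(nodes, if (length(edges)) dplyr::bind_rows(edges) else NULL,
                    type = "coupling")
}

#' Extract maximal consecutive metabolic routes
#'
#' Returns all maximum-cardinality simple paths of the coupling graph. On
#' graphs with at most `max_exact_nodes` nodes the search is exhaustive
#' (depth-first over all simple paths); larger graphs fall back to a greedy
#' beam search with a warning. Routes are canonicalized so the smaller
#' endpoint (EC identifiers compare by their numeric fields) comes first, the
#' link between consecutive steps is the smallest provenance compound of that
#' edge, and the route list is sorted.
#'
#' @param graph a coupling graph from [build_coupling_graph()].
#' @param max_exact_nodes node-count bound for the exhaustive search.
#' @param beam_width beam width of the fallback search.
#' @return A list of `metabolic_route` objects (fields `steps`, `links`).
#' @export
extract_routes <- function(graph, max_exact_nodes = 50L, beam_width = 200L) {
  stopifnot(inherits(graph, "crosstalk_network"))
  g <- as_adjacency(graph)
  if (!length(g$ids)) return(list())
  if (length(g$ids) <= max_exact_nodes) {
    paths <- all_longest_paths(g)
  } else {
    warning("coupling graph has ", length(g$ids), " nodes (> ", max_exact_nodes,
            "); using greedy beam search, routes may be suboptimal")
    paths <- beam_longest_paths(g, beam_width)
  }
  prov <- edge_provenance_map(graph)
  routes <- lapply(paths, function(p) {
    steps <- g$ids[p]
    if (length(steps) > 1L &&
        node_sort_key(steps[length(steps)]) < node_sort_key(steps[1L])) {
      steps <- rev(steps)
    }
    links <- if (length(steps) > 1L) {
      vapply(seq_len(length(steps) - 1L), function(k) {
        key <- edge_key(steps[k], steps[k + 1L])
        min(prov[[key]])
      }, character(1))
    } else character()
    structure(list(steps = steps, links = links), class = "metabolic_route")
  })
  keys <- vapply(routes, function(r) paste(node_sort_key(r$steps), collapse = "\r"),
                 character(1))
  routes <- routes[!duplicated(keys)]
  routes[order(keys[!duplicated(keys)])]
}

edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

edge_provenance_map <- function(network) {
  e <- network$edges
  stats::setNames(e$provenance, edge_key(e$from, e$to))
}

#' @export
print.metabolic_route <- function(x, ...) {
  cat("<metabolic_route> ", length(x$steps), " steps\n", sep = "")
  for (i in seq_along(x$steps)) {
    cat("  ", i, ". ", x$steps[i], sep = "")
    if (i < length(x$steps)) cat("  --[", x$links[i], "]-->", sep = "")
    cat("\n")
  }
  invisible(x)
}

#' Tabulate a metabolic route with hormone crosstalk tags
#'
#' One row per step: the step index, EC, the linking metabolite to the next
#' step (NA for the last step), and the hormones whose annotated pathways
#' contain a reaction of the step's enzyme.
#'
#' @param route a `metabolic_route` from [extract_routes()].
#' @param db a [pathway_db()].
#' @param annotations tibble from [parse_hormone_annotations()].
#' @return A tibble `step`, `ec`, `link_to_next`, `hormones` (list column).
#' @export
route_report <- function(route, db, annotations) {
  stopifnot(inherits(route, "metabolic_route"), inherits(db, "pathway_db"))
  idx <- ec_compound_index(db, route$steps)
  hormones <- lapply(route$steps, function(ec) {
    pwys <- idx[[ec]]$pathways
    sort(unique(annotations$hormone[annotations$pathway_id %in% pwys]))
  })
  tibble::tibble(
    step = seq_along(route$steps),
    ec = route$steps,
    link_to_next = c(route$links, NA_character_),
    hormones = hormones)
}
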