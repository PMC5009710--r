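#' Build the TF co-target network
#'
#' Nodes are transcription factors; two TFs are joined when they share at
#' least one target gene (optionally restricted to a target filter, e.g. the
#' genes encoding crosstalk-network enzymes). Edge provenance is the set of
#' shared targets within the filter.
#'
#' @param regulation tibble from [parse_regulation_table()].
#' @param target_filter `"ALL"` or a character vector of target gene ids.
#' @return A [crosstalk_network()] of kind-`tf` nodes with `co_targets` edges.
#' @export
build_cotarget_network <- function(regulation, target_filter = "ALL") {
  regulation <- tibble::as_tibble(regulation)
  if (!identical(target_filter, "ALL")) {
    regulation <- regulation[regulation$target_gene_id %in% target_filter, , drop = FALSE]
  }
  tfs <- sort(unique(regulation$tf_gene_id))
  nodes <- tibble::tibble(id = tfs, kind = "tf")
  edges <- list()
  by_target <- split(regulation$tf_gene_id, regulation$target_gene_id)
  pair_prov <- list()
  for (target in names(by_target)) {
    members <- sort(unique(by_target[[target]]))
    if (length(members) < 2L) next
    for (i in seq_len(length(members) - 1L)) {
      for (j in (i + 1L):length(members)) {
        key <- paste(members[i], members[j], sep = "\r")
        pair_prov[[key]] <- c(pair_prov[[key]], target)
      }
    }
  }
  if (length(pair_prov)) {
    parts <- strsplit(names(pair_prov), "\r", fixed = TRUE)
    edges <- tibble::tibble(
      from = vapply(parts, `[[`, character(1), 1L),
      to = vapply(parts, `[[`, character(1), 2L),
      relation = "co_targets",
      provenance = lapply(unname(pair_prov), function(p) sort(unique(p))))
  } else edges <- NULL
  crosstalk_network(nodes, edges, type = "tf_cotarget")
}

#' Enumerate simple cycles of a network
#'
#' All simple cycles of length 3 to `max_len`, each reported once in
#' canonical form: rotated so the smallest node id comes first and oriented
#' toward the smaller second element. The search anchors each cycle at its
#' smallest node and only walks through larger nodes, so no duplicates arise.
#'
#' @param network a [crosstalk_network()] or igraph object.
#' @param max_len maximum cycle length (>= 3). A message is emitted when the
#'   cap truncates the enumeration.
#' @return A list of character vectors (node id sequences, no repeated
#'   closing node), sorted.
#' @export
enumerate_cycles <- function(network, max_len = 15L) {
  if (max_len < 3L) stop("max_len must be >= 3")
  g <- as_adjacency(network)
  n <- length(g$ids)
  cycles <- list()
  truncated <- FALSE
  path <- integer(n)
  on_path <- logical(n)
  for (s in seq_len(n)) {
    dfs <- function(u, depth) {
      path[depth] <<- u; on_path[u] <<- TRUE
      for (w in g$adj[[u]]) {
        if (w == s && depth >= 3L && path[2L] < path[depth]) {
          cycles[[length(cycles) + 1L]] <<- path[seq_len(depth)]
        } else if (w > s && !on_path[w]) {
          if (depth < max_len) dfs(w, depth + 1L) else truncated <<- TRUE
        }
      }
      on_path[u] <<- FALSE
    }
    dfs(s, 1L)
  }
  if (truncated) message("cycle enumeration truncated at max_len = ", max_len)
  out <- lapply(cycles, function(p) g$ids[p])
  out[order(vapply(out, function(p) paste(sprintf("%04d", length(p)),
                                          paste(p, collapse = "\r")), character(1)))]
}

#' Assemble circular control units from cycles
#'
#' Cycles are grouped by the transitive closure of "share at least one edge";
#' each group becomes a control unit whose members are the union of its
#' cycles' nodes and whose regulated enzyme genes are the co-target provenance
#' of the unit's internal edges intersected with `enzyme_gene_set`.
#'
#' @param cycles list from [enumerate_cycles()].
#' @param network the co-target network the cycles came from.
#' @param enzyme_gene_set gene ids encoding crosstalk-network enzymes.
#' @return A list of `control_unit` objects (fields `members`, `cycles`,
#'   `regulated_enzyme_genes`), sorted by member count descending.
#' @export
assemble_units <- function(cycles, network, enzyme_gene_set = character()) {
  stopifnot(inherits(network, "crosstalk_network"))
  if (!length(cycles)) return(list())
  cycle_edges <- lapply(cycles, function(p) {
    nxt <- c(p[-1], p[1])
    unique(edge_key(p, nxt))
  })
  parent <- uf_new(length(cycles))
  edge_owner <- list()
  for (i in seq_along(cycles)) {
    for (ek in cycle_edges[[i]]) {
      if (!is.null(edge_owner[[ek]])) parent <- uf_union(parent, edge_owner[[ek]], i)
      else edge_owner[[ek]] <- i
    }
  }
  roots <- vapply(seq_along(cycles), function(i) uf_find(parent, i), integer(1))
  prov <- edge_provenance_map(network)
  units <- lapply(split(seq_along(cycles), roots), function(members_idx) {
    members <- sort(unique(unlist(cycles[members_idx])))
    inner <- network$edges[network$edges$from %in% members &
                             network$edges$to %in% members, , drop = FALSE]
    targets <- sort(unique(unlist(inner$provenance)))
    structure(list(
      members = members,
      cycles = cycles[members_idx],
      regulated_enzyme_genes = intersect(targets, sort(enzyme_gene_set))),
      class = "control_unit")
  })
  units <- unname(units)
  units[order(-vapply(units, function(u) length(u$members), integer(1)),
              vapply(units, function(u) u$members[[1]], character(1)))]
}

#' @export
print.control_unit <- function(x, ...) {
  cat("<control_unit> ", length(x$members), " TFs, ", length(x$cycles),
      " cycle(s), ", length(x$regulated_enzyme_genes),
      " regulated enzyme gene(s)\n", sep = "")
  invisible(x)
}

#' Longest protein-interaction route within a control unit
#'
#' Finds the longest simple path of the protein-protein interaction graph
#' induced on the unit's members (exhaustive search; units are small). Ties
#' are resolved lexicographically after canonical orientation (smaller
#' endpoint first).
#'
#' @param unit a `control_unit` from [assemble_units()].
#' @param ppi tibble from [parse_ppi_table()].
#' @return Ordered character vector of TF ids; empty when the induced PPI
#'   graph has no edges.
#' @export
find_ppi_route <- function(unit, ppi) {
  stopifnot(inherits(unit, "control_unit"))
  ppi <- tibble::as_tibble(ppi)
  keep <- ppi$gene_a %in% unit$members & ppi$gene_b %in% unit$members
  ppi <- ppi[keep, , drop = FALSE]
  if (!nrow(ppi)) return(character())
  nodes <- tibble::tibble(id = sort(unique(c(ppi$gene_a, ppi$gene_b))), kind = "tf")
  net <- crosstalk_network(nodes, tibble::tibble(
    from = ppi$gene_a, to = ppi$gene_b, relation = "co_targets",
    provenance = as.list(rep("ppi", nrow(ppi)))), type = "ppi")
  g <- as_adjacency(net)
  paths <- all_longest_paths(g)
  routes <- lapply(paths, function(p) {
    steps <- g$ids[p]
    if (length(steps) > 1L && steps[length(steps)] < steps[1L]) steps <- rev(steps)
    steps
  })
  keys <- vapply(routes, paste, character(1), collapse = "\r")
  routes[[order(keys)[1]]]
}
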