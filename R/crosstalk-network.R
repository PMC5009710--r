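#' Typed node/edge network with edge provenance
#'
#' The container for every network this package builds: the genome-scale
#' enzyme correlation network (GECN), the hormone crosstalk subnetwork
#' (EAPCN), producer/consumer coupling graphs, and TF co-target networks.
#' Nodes carry a kind (`enzyme`, `hormone` or `tf`); undirected edges carry a
#' relation label (`shares_compound`, `acts_in` or `co_targets`) and a
#' non-empty provenance set (shared compound ids, pathway/role tags, or shared
#' target genes). Edges are canonicalized (smaller endpoint first, sorted), so
#' identical networks compare and serialize identically.
#'
#' @param nodes tibble with columns `id`, `kind`.
#' @param edges tibble with columns `from`, `to`, `relation`, `provenance`
#'   (list column of character vectors).
#' @param type short label for what the network is (e.g. `"gecn"`).
#' @return An object of class `crosstalk_network` with elements `nodes`,
#'   `edges` and attribute `network_type`.
#' @export
crosstalk_network <- function(nodes, edges = NULL, type = "generic") {
  nodes <- tibble::as_tibble(nodes)
  stopifnot(all(c("id", "kind") %in% names(nodes)))
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  nodes <- dplyr::arrange(nodes, .data$id)
  if (is.null(edges) || !nrow(edges)) {
    edges <- tibble::tibble(from = character(), to = character(),
                            relation = character(), provenance = list())
  } else {
    edges <- tibble::as_tibble(edges)
    stopifnot(all(c("from", "to", "relation", "provenance") %in% names(edges)))
    if (any(edges$from == edges$to)) stop("self-edges are not allowed")
    missing <- setdiff(c(edges$from, edges$to), nodes$id)
    if (length(missing)) {
      stop("edge endpoint(s) not in node set: ", paste(sort(missing), collapse = ", "))
    }
    if (any(vapply(edges$provenance, length, integer(1)) == 0L)) {
      stop("every edge must carry non-empty provenance")
    }
    swap <- edges$to < edges$from
    tmp <- edges$from[swap]; edges$from[swap] <- edges$to[swap]; edges$to[swap] <- tmp
    edges$provenance <- lapply(edges$provenance, function(p) sort(unique(p)))
    # collapse parallel edges of the same relation, pooling provenance
    edges <- edges |>
      dplyr::group_by(.data$from, .data$to, .data$relation) |>
      dplyr::summarise(provenance = list(sort(unique(unlist(.data$provenance)))),
                       .groups = "drop") |>
      dplyr::arrange(.data$from, .data$to, .data$relation)
  }
  structure(list(nodes = nodes, edges = edges),
            class = "crosstalk_network", network_type = type)
}

#' @export
print.crosstalk_network <- function(x, ...) {
  kinds <- table(x$nodes$kind)
  cat("<crosstalk_network:", attr(x, "network_type"), "> ",
      nrow(x$nodes), " nodes (",
      paste(names(kinds), unname(kinds), sep = "=", collapse = ", "),
      "), ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Convert a crosstalk network to an igraph object
#'
#' Node kind and edge relation/provenance travel as attributes; provenance
#' sets are collapsed with `"|"`.
#'
#' @param network a [crosstalk_network()].
#' @return An undirected [igraph::graph].
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "crosstalk_network"))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, nrow(network$nodes),
                            name = network$nodes$id, kind = network$nodes$kind)
  if (nrow(network$edges)) {
    g <- igraph::add_edges(
      g, rbind(network$edges$from, network$edges$to),
      relation = network$edges$relation,
      provenance = vapply(network$edges$provenance, paste, character(1), collapse = "|"))
  }
  igraph::set_graph_attr(g, "network_type", attr(network, "network_type"))
}

#' Write a network in SIF, GraphML or edge-TSV format
#'
#' SIF writes one `source<TAB>relation<TAB>target` line per edge. Edge-TSV
#' adds a provenance column (`|`-separated). GraphML goes through igraph and
#' carries node kind plus edge relation/provenance as attributes. All formats
#' are byte-stable for a fixed network because nodes and edges are kept in
#' canonical sorted order.
#'
#' @param network a [crosstalk_network()].
#' @param file output path.
#' @param format one of `"sif"`, `"graphml"`, `"tsv"`.
#' @return `file`, invisibly.
#' @export
write_network <- function(network, file, format = c("sif", "graphml", "tsv")) {
  stopifnot(inherits(network, "crosstalk_network"))
  format <- match.arg(format)
  e <- network$edges
  if (format == "sif") {
    readr::write_lines(paste(e$from, e$relation, e$to, sep = "\t"), file)
  } else if (format == "tsv") {
    lines <- c("from\trelation\tto\tprovenance",
               paste(e$from, e$relation, e$to,
                     vapply(e$provenance, paste, character(1), collapse = "|"),
                     sep = "\t"))
    readr::write_lines(lines, file)
  } else {
    igraph::write_graph(as_igraph(network), file, format = "graphml")
  }
  invisible(file)
}

#' Read a GraphML file written by [write_network()] back into a network
#'
#' @param file GraphML path.
#' @return A [crosstalk_network()].
#' @export
read_network_graphml <- function(file) {
  g <- igraph::read_graph(file, format = "graphml")
  nodes <- tibble::tibble(id = igraph::V(g)$name, kind = igraph::V(g)$kind)
  if (igraph::ecount(g)) {
    ends <- igraph::as_edgelist(g)
    edges <- tibble::tibble(
      from = ends[, 1], to = ends[, 2],
      relation = igraph::E(g)$relation,
      provenance = strsplit(igraph::E(g)$provenance, "|", fixed = TRUE))
  } else edges <- NULL
  type <- igraph::graph_attr(g, "network_type")
  crosstalk_network(nodes, edges, type = if (is.null(type)) "generic" else type)
}
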