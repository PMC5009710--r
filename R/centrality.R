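#' Parameters for the twelve centrality indices
#'
#' The topological indices here follow the cytoHubba conventions: Degree,
#' Clustering Coefficient, Betweenness, Stress, Closeness (harmonic, so
#' disconnected networks are handled), Eccentricity (reciprocal, so larger is
#' always more central), Radiality, Maximum Neighborhood Component (MNC),
#' Density of Maximum Neighborhood Component (DMNC), Maximal Clique
#' Centrality (MCC), BottleNeck, and Edge Percolated Component (EPC).
#'
#' @param dmnc_epsilon exponent of the DMNC denominator (edge count of the
#'   largest neighbourhood component divided by node count to this power).
#' @param epc_realizations Monte-Carlo realizations for EPC.
#' @param epc_keep_probability probability an edge survives a percolation
#'   realization.
#' @param epc_seed RNG seed for EPC.
#' @param bottleneck_fraction a node is a bottleneck for a source when its
#'   BFS-tree descendant count exceeds this fraction of the tree size.
#' @param clique_guard_nodes abort maximal-clique enumeration above this size.
#' @return A list of class `centrality_params`.
#' @export
centrality_params <- function(dmnc_epsilon = 1.7,
                              epc_realizations = 1000L,
                              epc_keep_probability = 0.5,
                              epc_seed = 1L,
                              bottleneck_fraction = 0.25,
                              clique_guard_nodes = 5000L) {
  stopifnot(dmnc_epsilon > 0, epc_realizations >= 1,
            epc_keep_probability > 0, epc_keep_probability <= 1,
            bottleneck_fraction > 0)
  structure(list(dmnc_epsilon = dmnc_epsilon,
                 epc_realizations = as.integer(epc_realizations),
                 epc_keep_probability = epc_keep_probability,
                 epc_seed = as.integer(epc_seed),
                 bottleneck_fraction = bottleneck_fraction,
                 clique_guard_nodes = as.integer(clique_guard_nodes)),
            class = "centrality_params")
}

#' Local indices: degree and clustering coefficient
#'
#' Degree is the neighbour count; the clustering coefficient of a node with
#' `k` neighbours is `2 * (edges among neighbours) / (k * (k - 1))`, defined
#' as 0 when `k < 2`.
#'
#' @param network a [crosstalk_network()], igraph object, or edge list.
#' @return A tibble `node`, `degree`, `clustering_coefficient`.
#' @export
compute_local_indices <- function(network) {
  g <- as_adjacency(network)
  n <- length(g$ids)
  deg <- lengths(g$adj)
  cc <- vapply(seq_len(n), function(v) {
    k <- deg[v]
    if (k < 2L) return(0)
    nb <- g$adj[[v]]
    m <- 0L
    for (i in seq_len(k - 1L)) {
      m <- m + sum(g$adj[[nb[i]]] %in% nb[(i + 1L):k])
    }
    2 * m / (k * (k - 1))
  }, numeric(1))
  tibble::tibble(node = g$ids, degree = as.numeric(deg), clustering_coefficient = cc)
}

#' Shortest-path indices: betweenness, stress, closeness, eccentricity, radiality
#'
#' Betweenness sums, over unordered node pairs, the fraction of shortest paths
#' through the node; stress sums the raw counts. Closeness is harmonic
#' (`sum of 1/d` over reachable nodes). The eccentricity score is the
#' reciprocal of the largest distance within the node's component (0 for
#' isolated nodes). Radiality is `mean over the component of
#' (diameter + 1 - d(v, u))`, again 0 for isolated nodes.
#'
#' @inheritParams compute_local_indices
#' @return A tibble `node`, `betweenness`, `stress`, `closeness`,
#'   `eccentricity_score`, `radiality`.
#' @export
compute_path_indices <- function(network) {
  g <- as_adjacency(network)
  n <- length(g$ids)
  if (n == 0L) {
    return(tibble::tibble(node = character(), betweenness = numeric(),
                          stress = numeric(), closeness = numeric(),
                          eccentricity_score = numeric(), radiality = numeric()))
  }
  D <- matrix(-1L, n, n)
  S <- matrix(0, n, n)
  for (s in seq_len(n)) {
    bs <- bfs_dist_sigma(g, s)
    D[s, ] <- bs$dist
    S[s, ] <- bs$sigma
  }
  comp <- graph_components(g)
  betw <- numeric(n); stress <- numeric(n)
  for (v in seq_len(n)) {
    same <- which(comp == comp[v])
    others <- setdiff(same, v)
    if (length(others) < 2L) next
    for (ii in seq_len(length(others) - 1L)) {
      s <- others[ii]
      for (jj in (ii + 1L):length(others)) {
        t <- others[jj]
        if (D[s, v] + D[v, t] == D[s, t]) {
          through <- S[s, v] * S[v, t]
          stress[v] <- stress[v] + through
          betw[v] <- betw[v] + through / S[s, t]
        }
      }
    }
  }
  close <- vapply(seq_len(n), function(v) {
    d <- D[v, ]
    sum(1 / d[d > 0L])
  }, numeric(1))
  ecc <- numeric(n); radial <- numeric(n)
  for (v in seq_len(n)) {
    members <- which(comp == comp[v])
    if (length(members) == 1L) next
    dmax_v <- max(D[v, members])
    ecc[v] <- 1 / dmax_v
    diam <- max(D[members, members])
    others <- setdiff(members, v)
    radial[v] <- sum(diam + 1 - D[v, others]) / (length(members) - 1L)
  }
  tibble::tibble(node = g$ids, betweenness = betw, stress = stress,
                 closeness = close, eccentricity_score = ecc, radiality = radial)
}

#' Neighbourhood indices: MNC, DMNC and MCC
#'
#' MNC is the node count of the largest connected component of the subgraph
#' induced by the node's neighbours; DMNC divides that component's edge count
#' by its node count raised to `dmnc_epsilon`; MCC sums `(|C| - 1)!` over the
#' maximal cliques `C` containing the node (enumerated exhaustively,
#' Bron-Kerbosch style). Isolated nodes score 0 on all three.
#'
#' @inheritParams compute_local_indices
#' @param params a [centrality_params()].
#' @return A tibble `node`, `mnc`, `dmnc`, `mcc`.
#' @export
compute_neighborhood_indices <- function(network, params = centrality_params()) {
  g <- as_adjacency(network)
  n <- length(g$ids)
  mnc <- numeric(n); dmnc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- g$adj[[v]]
    if (!length(nb)) next
    sub <- induced_adjacency(g, nb)
    comp <- graph_components(sub)
    sizes <- table(comp)
    big <- as.integer(names(sizes)[which.max(sizes)])
    members <- which(comp == big)
    mnc[v] <- length(members)
    inner <- induced_adjacency(sub, members)
    dmnc[v] <- adjacency_edge_count(inner) / (length(members)^params$dmnc_epsilon)
  }
  mcc <- numeric(n)
  if (adjacency_edge_count(g) > 0) {
    cliques <- maximal_cliques_bk(g, params$clique_guard_nodes)
    for (cl in cliques) {
      if (length(cl) < 2L) next
      mcc[cl] <- mcc[cl] + factorial(length(cl) - 1L)
    }
  }
  tibble::tibble(node = g$ids, mnc = mnc, dmnc = dmnc, mcc = mcc)
}

#' BottleNeck centrality
#'
#' For each source node, a deterministic BFS shortest-path tree is built
#' (each node's parent is the smallest-id neighbour one level closer to the
#' source). A non-source node is a bottleneck for that source when its
#' descendant count (itself included) exceeds `bottleneck_fraction` times the
#' tree's node count. A node's BottleNeck score is the number of sources for
#' which it is a bottleneck.
#'
#' @inheritParams compute_neighborhood_indices
#' @return A tibble `node`, `bottleneck`.
#' @export
compute_bottleneck <- function(network, params = centrality_params()) {
  g <- as_adjacency(network)
  n <- length(g$ids)
  score <- numeric(n)
  for (s in seq_len(n)) {
    dist <- bfs_dist_sigma(g, s)$dist
    tree <- which(dist >= 0L)
    if (length(tree) < 2L) next
    parent <- rep(NA_integer_, n)
    for (w in tree) {
      if (w == s) next
      cand <- g$adj[[w]][dist[g$adj[[w]]] == dist[w] - 1L]
      parent[w] <- min(cand)  # adjacency is in index order; ids are sorted
    }
    count <- rep(1L, n)
    for (w in tree[order(dist[tree], decreasing = TRUE)]) {
      if (w == s) next
      count[parent[w]] <- count[parent[w]] + count[w]
    }
    threshold <- params$bottleneck_fraction * length(tree)
    hits <- setdiff(tree[count[tree] > threshold], s)
    score[hits] <- score[hits] + 1
  }
  tibble::tibble(node = g$ids, bottleneck = score)
}

#' Edge Percolated Component (EPC)
#'
#' Monte-Carlo percolation: in each realization every edge is deleted
#' independently with probability `1 - epc_keep_probability`; a node's score
#' for the realization is the size of its surviving component divided by the
#' total node count, and EPC is the mean over realizations. Reproducible for
#' a fixed `epc_seed`; with keep probability 1 it equals the component
#' fraction exactly.
#'
#' @inheritParams compute_neighborhood_indices
#' @return A tibble `node`, `epc`.
#' @export
compute_epc <- function(network, params = centrality_params()) {
  g <- as_adjacency(network)
  n <- length(g$ids)
  if (params$epc_realizations < 1L) stop("epc_realizations must be >= 1")
  if (n == 0L) return(tibble::tibble(node = character(), epc = numeric()))
  el <- do.call(rbind, lapply(seq_len(n), function(u) {
    nb <- g$adj[[u]]; nb <- nb[nb > u]
    if (length(nb)) cbind(u, nb) else NULL
  }))
  m <- if (is.null(el)) 0L else nrow(el)
  acc <- numeric(n)
  withr::with_seed(params$epc_seed, {
    for (r in seq_len(params$epc_realizations)) {
      keep <- if (m) stats::runif(m) <= params$epc_keep_probability else logical()
      parent <- uf_new(n)
      if (m && any(keep)) {
        kept <- which(keep)
        for (k in kept) parent <- uf_union(parent, el[k, 1], el[k, 2])
      }
      roots <- vapply(seq_len(n), function(x) uf_find(parent, x), integer(1))
      sizes <- table(roots)
      acc <- acc + as.numeric(sizes[as.character(roots)]) / n
    }
  })
  tibble::tibble(node = g$ids, epc = acc / params$epc_realizations)
}

#' Compute the full twelve-index centrality table
#'
#' Combines [compute_local_indices()], [compute_path_indices()],
#' [compute_neighborhood_indices()], [compute_bottleneck()] and
#' [compute_epc()] and adds dense ranks (1 = most central; ties share a rank)
#' for each index as `rank_<index>` columns.
#'
#' @inheritParams compute_neighborhood_indices
#' @return A tibble of class `centrality_table`: `node`, twelve score
#'   columns, twelve rank columns.
#' @export
compute_centrality <- function(network, params = centrality_params()) {
  tab <- compute_local_indices(network) |>
    dplyr::left_join(compute_path_indices(network), by = "node") |>
    dplyr::left_join(compute_neighborhood_indices(network, params), by = "node") |>
    dplyr::left_join(compute_bottleneck(network, params), by = "node") |>
    dplyr::left_join(compute_epc(network, params), by = "node")
  tab <- tab[, c("node", centrality_index_names())]
  for (idx in centrality_index_names()) {
    tab[[paste0("rank_", idx)]] <- dplyr::dense_rank(dplyr::desc(tab[[idx]]))
  }
  class(tab) <- c("centrality_table", class(tab))
  attr(tab, "params") <- params
  tab
}

#' @rdname compute_centrality
#' @export
centrality_index_names <- function() {
  c("degree", "mcc", "dmnc", "mnc", "epc", "bottleneck", "eccentricity_score",
    "closeness", "radiality", "betweenness", "stress", "clustering_coefficient")
}

#' Select hub nodes from a centrality table
#'
#' A node is a hub when it sits within the top `k` positions for at least `m`
#' of the twelve indices. Positions are ordinal: nodes are ordered by score
#' descending with ties broken by node id ascending.
#'
#' @param table a `centrality_table` from [compute_centrality()].
#' @param k top-list depth per index.
#' @param m minimum number of indices (1-12) a hub must appear in.
#' @return Sorted character vector of hub node ids.
#' @export
rank_and_select_hubs <- function(table, k, m) {
  if (k < 1) stop("k must be >= 1")
  stopifnot(m >= 1, m <= 12)
  counts <- stats::setNames(integer(nrow(table)), table$node)
  for (idx in centrality_index_names()) {
    ord <- order(-table[[idx]], table$node)
    top <- table$node[ord][seq_len(min(k, nrow(table)))]
    counts[top] <- counts[top] + 1L
  }
  sort(names(counts)[counts >= m])
}
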