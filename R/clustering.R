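#' Parameters for cohesiveness-based overlapping clustering
#'
#' @param penalty size penalty `p` in the cohesiveness denominator.
#' @param merge_overlap minimum overlap score `|A∩B|^2 / (|A|·|B|)` at which
#'   two clusters are merged.
#' @param min_size minimum member count of a reported cluster.
#' @param min_density minimum internal edge density of a reported cluster.
#' @return A list of class `cluster_params`.
#' @export
cluster_params <- function(penalty = 2, merge_overlap = 0.8,
                           min_size = 3L, min_density = 0.5) {
  stopifnot(penalty >= 0, merge_overlap > 0, merge_overlap <= 1,
            min_size >= 1, min_density >= 0, min_density <= 1)
  structure(list(penalty = penalty, merge_overlap = merge_overlap,
                 min_size = as.integer(min_size), min_density = min_density),
            class = "cluster_params")
}

# internal: edge counts for a candidate set (indexes)
set_edge_counts <- function(g, members) {
  inside <- logical(length(g$ids)); inside[members] <- TRUE
  w_in <- 0L; w_bound <- 0L
  for (u in members) {
    for (w in g$adj[[u]]) {
      if (inside[w]) { if (w > u) w_in <- w_in + 1L } else w_bound <- w_bound + 1L
    }
  }
  list(w_in = w_in, w_bound = w_bound)
}

#' Cohesiveness of a node set
#'
#' `w_in / (w_in + w_bound + p * |V|)` where `w_in` counts edges with both
#' ends inside the set and `w_bound` edges with exactly one end inside
#' (unit edge weights). Higher is better: a cohesive cluster has many internal
#' and few boundary edges, with the `p·|V|` term penalising loose growth.
#'
#' @param network a [crosstalk_network()], igraph object, or adjacency.
#' @param node_set character vector of node ids (non-empty).
#' @param penalty non-negative size penalty `p`.
#' @return A number in `[0, 1]`.
#' @export
cohesiveness <- function(network, node_set, penalty = 2) {
  g <- as_adjacency(network)
  if (!length(node_set)) stop("node_set must be non-empty")
  members <- match(node_set, g$ids)
  if (anyNA(members)) stop("node(s) not in network: ",
                           paste(node_set[is.na(members)], collapse = ", "))
  cnt <- set_edge_counts(g, members)
  denom <- cnt$w_in + cnt$w_bound + penalty * length(members)
  if (denom == 0) 0 else cnt$w_in / denom
}

cluster_density <- function(g, members) {
  k <- length(members)
  if (k < 2L) return(0)
  set_edge_counts(g, members)$w_in / (k * (k - 1) / 2)
}

#' Grow one cluster from a seed by greedy cohesiveness improvement
#'
#' Best-improvement local search: at each step the single boundary-node
#' addition or non-seed member removal that most increases cohesiveness is
#' applied; growth stops at a local maximum. Ties are broken by node id
#' ascending, so the procedure is deterministic.
#'
#' @inheritParams cohesiveness
#' @param seed_node starting node id.
#' @param params a [cluster_params()].
#' @return A list of class `cluster`: `members` (sorted ids), `cohesiveness`,
#'   `density`.
#' @export
grow_cluster <- function(network, seed_node, params = cluster_params()) {
  g <- as_adjacency(network)
  s <- match(seed_node, g$ids)
  if (is.na(s)) stop("seed node not in network: ", seed_node)
  members <- s
  current <- cohesiveness_idx(g, members, params$penalty)
  repeat {
    boundary <- sort(setdiff(unique(unlist(g$adj[members])), members))
    removable <- setdiff(members, s)
    cand <- c(lapply(boundary, function(v) list(set = sort(c(members, v)), node = v)),
              lapply(removable, function(v) list(set = setdiff(members, v), node = v)))
    if (!length(cand)) break
    vals <- vapply(cand, function(cc) cohesiveness_idx(g, cc$set, params$penalty), numeric(1))
    best <- max(vals)
    if (best <= current + 1e-12) break
    winners <- which(vals == best)
    ids <- vapply(winners, function(w) g$ids[cand[[w]]$node], character(1))
    pick <- winners[order(ids)][1]
    members <- cand[[pick]]$set
    current <- best
  }
  new_cluster(g, members, params$penalty)
}

cohesiveness_idx <- function(g, members, penalty) {
  cnt <- set_edge_counts(g, members)
  denom <- cnt$w_in + cnt$w_bound + penalty * length(members)
  if (denom == 0) 0 else cnt$w_in / denom
}

new_cluster <- function(g, members, penalty) {
  structure(list(members = g$ids[sort(members)],
                 cohesiveness = cohesiveness_idx(g, members, penalty),
                 density = cluster_density(g, members)),
            class = "cluster")
}

#' @export
print.cluster <- function(x, ...) {
  cat("<cluster> ", length(x$members), " members, cohesiveness ",
      signif(x$cohesiveness, 4), ", density ", signif(x$density, 4), "\n",
      sep = "")
  invisible(x)
}

#' Detect overlapping clusters by seeded cohesiveness growth
#'
#' Seeds are processed in degree-descending order (ties by id), skipping nodes
#' already covered by an earlier grown cluster. Grown clusters are merged to a
#' fixed point whenever a pair overlaps by at least `merge_overlap`
#' (overlap score `|A∩B|^2 / (|A|·|B|)`; merged clusters are unions with
#' cohesiveness recomputed). Clusters smaller than `min_size` or sparser than
#' `min_density` are then discarded.
#'
#' @inheritParams grow_cluster
#' @return A tibble of class `cluster_set`, sorted by cohesiveness descending,
#'   with columns `members` (list), `size`, `cohesiveness`, `density`.
#' @export
detect_clusters <- function(network, params = cluster_params()) {
  g <- as_adjacency(network)
  n <- length(g$ids)
  empty <- tibble::tibble(members = list(), size = integer(),
                          cohesiveness = numeric(), density = numeric())
  class(empty) <- c("cluster_set", class(empty))
  if (n == 0L) return(empty)
  deg <- lengths(g$adj)
  order_seeds <- order(-deg, g$ids)
  covered <- logical(n)
  grown <- list()
  for (s in order_seeds) {
    if (covered[s]) next
    cl <- grow_cluster(g, g$ids[s], params)
    members <- match(cl$members, g$ids)
    covered[members] <- TRUE
    key <- paste(members, collapse = ",")
    if (!length(grown) || !key %in% names(grown)) grown[[key]] <- members
  }
  sets <- unname(grown)
  # merge to a fixed point
  repeat {
    merged <- FALSE
    if (length(sets) >= 2L) {
      for (i in seq_len(length(sets) - 1L)) {
        for (j in (i + 1L):length(sets)) {
          ov <- length(intersect(sets[[i]], sets[[j]]))^2 /
            (length(sets[[i]]) * length(sets[[j]]))
          if (ov >= params$merge_overlap) {
            sets[[i]] <- sort(union(sets[[i]], sets[[j]]))
            sets[[j]] <- NULL
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
    }
    if (!merged) break
  }
  keep <- Filter(function(m) length(m) >= params$min_size &&
                   cluster_density(g, m) >= params$min_density, sets)
  if (!length(keep)) return(empty)
  out <- tibble::tibble(
    members = lapply(keep, function(m) g$ids[m]),
    size = vapply(keep, length, integer(1)),
    cohesiveness = vapply(keep, function(m) cohesiveness_idx(g, m, params$penalty), numeric(1)),
    density = vapply(keep, function(m) cluster_density(g, m), numeric(1)))
  out <- out[order(-out$cohesiveness,
                   vapply(out$members, function(m) m[[1]], character(1))), ]
  class(out) <- c("cluster_set", class(out))
  out
}
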