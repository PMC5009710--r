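# Minimal internal adjacency representation used by the centrality,
# clustering, route and cycle code. Node ids are kept sorted; adjacency lists
# hold integer indexes into `ids`, sorted ascending, which makes every
# traversal deterministic.

as_adjacency <- function(network) {
  if (inherits(network, "crosstalk_network")) {
    ids <- network$nodes$id
    from <- network$edges$from
    to <- network$edges$to
  } else if (inherits(network, "igraph")) {
    ids <- igraph::V(network)$name
    if (is.null(ids)) ids <- as.character(seq_len(igraph::vcount(network)))
    el <- igraph::as_edgelist(network, names = TRUE)
    from <- as.character(el[, 1]); to <- as.character(el[, 2])
  } else if (is.list(network) && !is.null(network$ids) && !is.null(network$adj)) {
    return(network)
  } else {
    stop("cannot interpret object as a graph")
  }
  ord <- order(ids)
  ids <- ids[ord]
  n <- length(ids)
  idx <- stats::setNames(seq_len(n), ids)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer()
  if (length(from)) {
    fi <- idx[from]; ti <- idx[to]
    keep <- fi != ti
    fi <- fi[keep]; ti <- ti[keep]
    for (k in seq_along(fi)) {
      adj[[fi[k]]] <- c(adj[[fi[k]]], ti[k])
      adj[[ti[k]]] <- c(adj[[ti[k]]], fi[k])
    }
    adj <- lapply(adj, function(v) sort(unique(v)))
  }
  list(ids = ids, adj = adj)
}

adjacency_edge_count <- function(g) sum(lengths(g$adj)) / 2

# BFS distances and shortest-path counts from source s (index).
bfs_dist_sigma <- function(g, s) {
  n <- length(g$ids)
  dist <- rep(-1L, n); sigma <- numeric(n)
  dist[s] <- 0L; sigma[s] <- 1
  frontier <- s
  while (length(frontier)) {
    nxt <- integer()
    for (u in frontier) {
      for (w in g$adj[[u]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[u] + 1L
          nxt <- c(nxt, w)
        }
        if (dist[w] == dist[u] + 1L) sigma[w] <- sigma[w] + sigma[u]
      }
    }
    frontier <- sort(unique(nxt))
  }
  list(dist = dist, sigma = sigma)
}

# Connected-component membership (integer labels, deterministic).
graph_components <- function(g) {
  n <- length(g$ids)
  comp <- rep(0L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s; comp[s] <- cur
    while (length(queue)) {
      u <- queue[[1]]; queue <- queue[-1]
      for (w in g$adj[[u]]) if (comp[w] == 0L) { comp[w] <- cur; queue <- c(queue, w) }
    }
  }
  comp
}

# Induced subgraph on a set of indexes; returns adjacency over the subset
# (ids keep their original labels).
induced_adjacency <- function(g, keep) {
  keep <- sort(keep)
  remap <- integer(length(g$ids)); remap[keep] <- seq_along(keep)
  adj <- lapply(keep, function(u) {
    nb <- g$adj[[u]]
    sort(remap[nb[nb %in% keep]])
  })
  list(ids = g$ids[keep], adj = adj)
}

# Bron-Kerbosch maximal clique enumeration with pivoting. Returns a list of
# integer index vectors (sorted). Guarded: centrality over cliques is meant
# for hormone-pathway-scale graphs, not genome hairballs.
maximal_cliques_bk <- function(g, max_nodes = 5000L) {
  n <- length(g$ids)
  if (n > max_nodes) {
    stop("maximal clique enumeration aborted: graph has ", n,
         " nodes (> guard of ", max_nodes, ")")
  }
  out <- list()
  nb <- g$adj
  expand <- function(R, P, X) {
    if (!length(P) && !length(X)) {
      out[[length(out) + 1L]] <<- sort(R)
      return(invisible())
    }
    pivot_pool <- c(P, X)
    deg_in_p <- vapply(pivot_pool, function(u) length(intersect(nb[[u]], P)), integer(1))
    pivot <- pivot_pool[[which.max(deg_in_p)]]
    for (v in setdiff(P, nb[[pivot]])) {
      expand(c(R, v), intersect(P, nb[[v]]), intersect(X, nb[[v]]))
      P <- setdiff(P, v)
      X <- c(X, v)
    }
  }
  expand(integer(), seq_len(n), integer())
  out
}

# Exhaustive longest-simple-path search by DFS. Returns all maximum paths as
# index vectors, deduplicated by orientation (each undirected path reported
# once, in both-direction canonical form decided by the caller).
all_longest_paths <- function(g) {
  n <- length(g$ids)
  if (n == 0L) return(list())
  best_len <- 1L
  best <- lapply(seq_len(n), function(i) i)
  path <- integer(n)
  on_path <- logical(n)
  results <- list()
  dfs <- function(u, depth) {
    path[depth] <<- u; on_path[u] <<- TRUE
    extended <- FALSE
    for (w in g$adj[[u]]) {
      if (!on_path[w]) {
        extended <- TRUE
        dfs(w, depth + 1L)
      }
    }
    if (depth > best_len) {
      best_len <<- depth
      results <<- list(path[seq_len(depth)])
    } else if (depth == best_len && depth > 1L) {
      results[[length(results) + 1L]] <<- path[seq_len(depth)]
    }
    on_path[u] <<- FALSE
  }
  for (s in seq_len(n)) dfs(s, 1L)
  if (best_len == 1L) return(best)
  # each path appears once per direction; dedupe on canonical key
  keys <- vapply(results, function(p) {
    a <- paste(p, collapse = ","); b <- paste(rev(p), collapse = ",")
    if (a < b) a else b
  }, character(1))
  results[!duplicated(keys)]
}

# Greedy beam search fallback for longest simple paths on large graphs.
beam_longest_paths <- function(g, beam_width = 200L) {
  n <- length(g$ids)
  beams <- lapply(seq_len(n), function(i) i)
  best <- beams
  repeat {
    nxt <- list()
    for (p in beams) {
      tail <- p[length(p)]
      for (w in g$adj[[tail]]) if (!(w %in% p)) nxt[[length(nxt) + 1L]] <- c(p, w)
    }
    if (!length(nxt)) break
    keys <- vapply(nxt, function(p) paste(p, collapse = ","), character(1))
    nxt <- nxt[!duplicated(keys)]
    ord <- order(vapply(nxt, function(p) paste(sprintf("%06d", p), collapse = ","), character(1)))
    nxt <- nxt[ord]
    if (length(nxt) > beam_width) nxt <- nxt[seq_len(beam_width)]
    best <- nxt
    beams <- nxt
  }
  len <- max(vapply(best, length, integer(1)))
  best <- best[vapply(best, length, integer(1)) == len]
  keys <- vapply(best, function(p) {
    a <- paste(p, collapse = ","); b <- paste(rev(p), collapse = ",")
    if (a < b) a else b
  }, character(1))
  best[!duplicated(keys)]
}

# Disjoint-set union-find.
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, x) {
  while (parent[x] != x) x <- parent[x]
  x
}
uf_union <- function(parent, a, b) {
  ra <- uf_find(parent, a); rb <- uf_find(parent, b)
  if (ra != rb) parent[rb] <- ra
  parent
}
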