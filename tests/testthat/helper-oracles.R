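# Independent brute-force oracles used to verify the network statistics.
# These deliberately avoid the package's internal graph machinery: paths and
# cliques are enumerated from the raw edge list.

# Random simple graph as a crosstalk_network (enzyme nodes, unit provenance).
rand_network <- function(n, p, seed, prefix = "n") {
  withr::with_seed(seed, {
    ids <- sprintf("%s%02d", prefix, seq_len(n))
    pairs <- if (n >= 2) t(utils::combn(ids, 2)) else matrix(character(), 0, 2)
    keep <- stats::runif(nrow(pairs)) < p
    edges <- if (any(keep)) {
      tibble::tibble(from = pairs[keep, 1], to = pairs[keep, 2],
                     relation = "shares_compound",
                     provenance = as.list(rep("x", sum(keep))))
    } else NULL
    crosstalk_network(tibble::tibble(id = ids, kind = "enzyme"), edges)
  })
}

net_adj_list <- function(net) {
  ids <- net$nodes$id
  adj <- stats::setNames(lapply(ids, function(i) character()), ids)
  for (k in seq_len(nrow(net$edges))) {
    a <- net$edges$from[k]; b <- net$edges$to[k]
    adj[[a]] <- sort(c(adj[[a]], b)); adj[[b]] <- sort(c(adj[[b]], a))
  }
  adj
}

# all simple paths between two named nodes
oracle_enum_paths <- function(adj, s, t) {
  res <- list()
  dfs <- function(path) {
    u <- path[length(path)]
    if (u == t) { res[[length(res) + 1L]] <<- path; return(invisible()) }
    for (w in adj[[u]]) if (!(w %in% path)) dfs(c(path, w))
  }
  dfs(s)
  res
}

# betweenness / stress / harmonic closeness / reciprocal eccentricity /
# radiality from exhaustive path enumeration
oracle_path_stats <- function(net) {
  adj <- net_adj_list(net)
  ids <- names(adj)
  n <- length(ids)
  D <- matrix(Inf, n, n, dimnames = list(ids, ids)); diag(D) <- 0
  shortest <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    paths <- oracle_enum_paths(adj, ids[i], ids[j])
    if (!length(paths)) next
    lens <- vapply(paths, length, integer(1)) - 1L
    D[i, j] <- min(lens)
    shortest[[paste(i, j)]] <- paths[lens == min(lens)]
  }
  betw <- stats::setNames(numeric(n), ids)
  stress <- betw
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sp <- shortest[[paste(i, j)]]
    if (is.null(sp)) next
    for (v in ids[-c(i, j)]) {
      cnt <- sum(vapply(sp, function(p) v %in% p, logical(1)))
      stress[v] <- stress[v] + cnt
      betw[v] <- betw[v] + cnt / length(sp)
    }
  }
  close <- vapply(seq_len(n), function(i) {
    d <- D[i, -i]; sum(1 / d[is.finite(d)])
  }, numeric(1))
  ecc <- numeric(n); radial <- numeric(n)
  for (i in seq_len(n)) {
    comp <- which(is.finite(D[i, ]))
    if (length(comp) == 1L) next
    ecc[i] <- 1 / max(D[i, comp])
    diam <- max(D[comp, comp])
    others <- setdiff(comp, i)
    radial[i] <- mean(diam + 1 - D[i, others])
  }
  tibble::tibble(node = ids, betweenness = unname(betw), stress = unname(stress),
                 closeness = close, eccentricity_score = ecc, radiality = radial)
}

# MCC / MNC / DMNC from subset enumeration (n <= ~12)
oracle_neighborhood_stats <- function(net, epsilon = 1.7) {
  adj <- net_adj_list(net)
  ids <- names(adj)
  n <- length(ids)
  is_clique <- function(set) {
    if (length(set) < 2L) return(FALSE)
    all(vapply(seq_along(set), function(a) {
      all(setdiff(set, set[a]) %in% adj[[set[a]]])
    }, logical(1)))
  }
  cliques <- list()
  for (k in 2:max(2, n)) {
    if (k > n) break
    sets <- utils::combn(ids, k, simplify = FALSE)
    for (s in sets) {
      if (!is_clique(s)) next
      ext <- setdiff(ids, s)
      maximal <- !any(vapply(ext, function(v) all(s %in% adj[[v]]), logical(1)))
      if (maximal) cliques[[length(cliques) + 1L]] <- s
    }
  }
  mcc <- stats::setNames(numeric(n), ids)
  for (cl in cliques) mcc[cl] <- mcc[cl] + factorial(length(cl) - 1L)
  comp_of <- function(members) {
    # components of induced subgraph, by repeated closure
    left <- members; comps <- list()
    while (length(left)) {
      cur <- left[1]
      repeat {
        nxt <- unique(c(cur, unlist(lapply(cur, function(u) intersect(adj[[u]], members)))))
        if (length(nxt) == length(cur)) break
        cur <- nxt
      }
      comps[[length(comps) + 1L]] <- sort(cur)
      left <- setdiff(left, cur)
    }
    comps
  }
  mnc <- stats::setNames(numeric(n), ids); dmnc <- mnc
  for (v in ids) {
    nb <- adj[[v]]
    if (!length(nb)) next
    comps <- comp_of(nb)
    sizes <- vapply(comps, length, integer(1))
    big <- comps[[which.max(sizes)]]
    mnc[v] <- length(big)
    ecount <- sum(vapply(seq_along(big), function(a) {
      sum(intersect(adj[[big[a]]], big) > big[a])
    }, numeric(1)))
    dmnc[v] <- ecount / length(big)^epsilon
  }
  tibble::tibble(node = ids, mnc = unname(mnc), dmnc = unname(dmnc), mcc = unname(mcc))
}

# all simple cycles (length >= 3) by permutation enumeration; canonical form:
# smallest id first, oriented toward the smaller second element
oracle_cycles <- function(net) {
  adj <- net_adj_list(net)
  ids <- names(adj)
  n <- length(ids)
  found <- character()
  out <- list()
  if (n >= 3) {
    for (k in 3:n) {
      for (set in utils::combn(ids, k, simplify = FALSE)) {
        anchor <- min(set)
        rest <- setdiff(set, anchor)
        perms <- perms_of(rest)
        for (p in perms) {
          cyc <- c(anchor, p)
          if (cyc[2] > cyc[k]) next  # orientation
          edges_ok <- all(vapply(seq_len(k), function(a) {
            cyc[(a %% k) + 1L] %in% adj[[cyc[a]]]
          }, logical(1)))
          if (edges_ok) {
            key <- paste(cyc, collapse = "\r")
            if (!key %in% found) { found <- c(found, key); out[[length(out) + 1L]] <- cyc }
          }
        }
      }
    }
  }
  out[order(vapply(out, function(p) paste(sprintf("%04d", length(p)),
                                          paste(p, collapse = "\r")), character(1)))]
}

perms_of <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in perms_of(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

# longest simple path length via igraph's independent path enumeration
oracle_longest_path_len <- function(net) {
  g <- as_igraph(net)
  if (igraph::ecount(g) == 0) return(min(1L, igraph::vcount(g)))
  best <- 1L
  for (v in igraph::V(g)) {
    sp <- igraph::all_simple_paths(g, from = v)
    if (length(sp)) best <- max(best, max(vapply(sp, length, integer(1))))
  }
  best
}

# tiny deterministic pathway db used by io round-trip tests
make_small_db <- function(seed = 1L) {
  withr::with_seed(seed, {
    cpd <- sprintf("C%02d", 1:8)
    compounds <- tibble::tibble(
      compound_id = cpd, name = paste("compound", cpd),
      synonyms = lapply(1:8, function(i) if (i %% 2) sprintf("syn-%d", i) else character()))
    pathways <- tibble::tibble(pathway_id = c("P1", "P2"), name = c("one", "two"))
    ecs <- c("1.1.1.1", "2.3.1.74", "6.3.-.-")
    reactions <- tibble::tibble(
      reaction_id = c("R1", "R2", "R3"),
      ec_numbers = list("1.1.1.1", c("2.3.1.74", "6.3.-.-"), "6.3.-.-"),
      substrate_ids = list(c("C01", "C02"), "C03", c("C04", "C05")),
      product_ids = list("C03", c("C04", "C06"), "C07"),
      reversible = c(FALSE, TRUE, FALSE),
      pathway_ids = list("P1", c("P1", "P2"), "P2"))
    enzymes <- tibble::tibble(
      enzyme_id = ecs, ec = ecs, display_name = paste("enzyme", ecs),
      gene_ids = list("AA1G00010", c("AA1G00020", "AA2G00030"), character()),
      protein_ids = list(character(), "PROT1", character()))
    pathway_db(compounds, reactions, enzymes, pathways)
  })
}

# clique-block network builder shared by the clustering and plot tests
clique_net <- function(sizes, extra_edges = NULL, isolated = character()) {
  ids <- character(); edges <- list()
  for (b in seq_along(sizes)) {
    mem <- sprintf("b%d_%02d", b, seq_len(sizes[b]))
    ids <- c(ids, mem)
    pr <- t(utils::combn(mem, 2))
    edges[[b]] <- tibble::tibble(from = pr[, 1], to = pr[, 2],
                                 relation = "shares_compound",
                                 provenance = as.list(rep("x", nrow(pr))))
  }
  e <- dplyr::bind_rows(edges)
  if (!is.null(extra_edges)) {
    e <- dplyr::bind_rows(e, tibble::tibble(
      from = extra_edges[, 1], to = extra_edges[, 2],
      relation = "shares_compound", provenance = as.list(rep("x", nrow(extra_edges)))))
  }
  crosstalk_network(tibble::tibble(id = c(ids, isolated), kind = "enzyme"), e)
}
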