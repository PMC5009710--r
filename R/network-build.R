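#' Currency metabolite policy
#'
#' Ubiquitous cofactors are excluded from edge formation so that shared-ATP or
#' shared-water links do not turn the enzyme network into a hairball. The
#' default set covers the classic currency metabolites; deliberately NOT in it
#' are S-adenosyl-L-methionine and UDP-D-glucose, which act as route-relevant
#' substrates in hormone conjugation and methylation pathways. The set is
#' fully configurable.
#'
#' @param currency_ids compound ids to exclude from edge formation.
#' @return An object of class `currency_policy`.
#' @export
currency_policy <- function(currency_ids = default_currency()) {
  structure(list(currency_ids = sort(unique(currency_ids))), class = "currency_policy")
}

#' @rdname currency_policy
#' @export
default_currency <- function() {
  c("WATER", "PROTON", "ATP", "ADP", "AMP", "PHOSPHATE", "DIPHOSPHATE",
    "NAD", "NADH", "NADP", "NADPH", "CARBON-DIOXIDE", "OXYGEN", "CO-A", "UDP")
}

check_policy <- function(policy, db) {
  if (is.null(policy)) policy <- currency_policy()
  stopifnot(inherits(policy, "currency_policy"))
  unknown <- setdiff(policy$currency_ids, db$compounds$compound_id)
  if (length(unknown)) {
    warning("currency compound id(s) not present in the database (ignored): ",
            paste(unknown, collapse = ", "))
  }
  policy
}

#' Build the genome-scale enzyme correlation network (GECN)
#'
#' Nodes are the database's enzymes, collapsed by EC string. Two distinct
#' enzymes are joined by an undirected edge when some non-currency compound
#' participates (on either reaction side) in at least one reaction of each;
#' the edge's provenance is the full set of such shared compounds.
#'
#' @param db a [pathway_db()].
#' @param policy a [currency_policy()]; `NULL` for the default set.
#' @return A [crosstalk_network()] of kind-`enzyme` nodes with
#'   `shares_compound` edges.
#' @export
build_gecn <- function(db, policy = NULL) {
  stopifnot(inherits(db, "pathway_db"))
  policy <- check_policy(policy, db)
  idx <- ec_compound_index(db)
  ecs <- names(idx)
  nodes <- tibble::tibble(id = ecs, kind = "enzyme")
  # invert: compound -> enzymes touching it
  by_compound <- new.env(parent = emptyenv())
  for (ec in ecs) {
    for (c_ in setdiff(idx[[ec]]$all, policy$currency_ids)) {
      assign(c_, c(get0(c_, envir = by_compound, ifnotfound = character()), ec),
             envir = by_compound)
    }
  }
  pair_prov <- list()
  for (c_ in ls(by_compound)) {
    members <- sort(unique(get(c_, envir = by_compound)))
    if (length(members) < 2L) next
    for (i in seq_len(length(members) - 1L)) {
      for (j in seq((i + 1L), length(members))) {
        key <- paste(members[i], members[j], sep = "\r")
        pair_prov[[key]] <- c(pair_prov[[key]], c_)
      }
    }
  }
  edges <- NULL
  if (length(pair_prov)) {
    keys <- names(pair_prov)
    parts <- strsplit(keys, "\r", fixed = TRUE)
    edges <- tibble::tibble(
      from = vapply(parts, `[[`, character(1), 1L),
      to = vapply(parts, `[[`, character(1), 2L),
      relation = "shares_compound",
      provenance = unname(pair_prov))
  }
  crosstalk_network(nodes, edges, type = "gecn")
}

#' Build the enzyme-based phytohormone crosstalk network (EAPCN)
#'
#' The EAPCN restricts the GECN to hormone-annotated pathways and adds one
#' hormone node per annotated hormone. An enzyme is included when it catalyses
#' at least one reaction in at least one annotated pathway; an enzyme-hormone
#' `acts_in` edge records the annotated pathway ids and roles as provenance
#' (`"pathway:role"` strings); enzyme-enzyme edges are the GECN edges
#' restricted to the included enzymes.
#'
#' @param db a [pathway_db()].
#' @param annotations tibble from [parse_hormone_annotations()].
#' @param policy a [currency_policy()]; `NULL` for the default set.
#' @return A [crosstalk_network()] with hormone and enzyme nodes.
#' @export
build_eapcn <- function(db, annotations, policy = NULL) {
  stopifnot(inherits(db, "pathway_db"))
  policy <- check_policy(policy, db)
  annotations <- tibble::as_tibble(annotations)
  if (!nrow(annotations)) {
    return(crosstalk_network(tibble::tibble(id = character(), kind = character()),
                             NULL, type = "eapcn"))
  }
  missing_pwy <- setdiff(unique(annotations$pathway_id), db$pathways$pathway_id)
  if (length(missing_pwy)) {
    stop("annotation(s) reference unknown pathway id(s): ",
         paste(sort(missing_pwy), collapse = ", "))
  }
  hormones <- sort(unique(annotations$hormone))
  idx <- ec_compound_index(db)
  acts <- list()
  included <- character()
  for (ec in names(idx)) {
    pwys <- idx[[ec]]$pathways
    hit <- annotations[annotations$pathway_id %in% pwys, , drop = FALSE]
    if (!nrow(hit)) next
    included <- c(included, ec)
    for (h in unique(hit$hormone)) {
      hh <- hit[hit$hormone == h, , drop = FALSE]
      acts[[length(acts) + 1L]] <- tibble::tibble(
        from = ec, to = h, relation = "acts_in",
        provenance = list(sort(unique(paste(hh$pathway_id, hh$role, sep = ":")))))
    }
  }
  nodes <- dplyr::bind_rows(
    tibble::tibble(id = hormones, kind = "hormone"),
    tibble::tibble(id = sort(included), kind = "enzyme"))
  gecn <- build_gecn(db, policy)
  ee <- gecn$edges[gecn$edges$from %in% included & gecn$edges$to %in% included, , drop = FALSE]
  edges <- dplyr::bind_rows(dplyr::bind_rows(acts), ee)
  crosstalk_network(nodes, if (nrow(edges)) edges else NULL, type = "eapcn")
}

#' Enzymes shared between two hormones' pathway neighbourhoods
#'
#' Returns the enzymes adjacent (via `acts_in` edges) to both hormone nodes of
#' an EAPCN — the crosstalk bridge set for the hormone pair.
#'
#' @param network an EAPCN from [build_eapcn()].
#' @param hormone_a,hormone_b hormone node ids (lower-case hormone names).
#' @return Sorted character vector of enzyme ids.
#' @export
shared_crosstalk_enzymes <- function(network, hormone_a, hormone_b) {
  stopifnot(inherits(network, "crosstalk_network"))
  h <- network$nodes$id[network$nodes$kind == "hormone"]
  for (x in c(hormone_a, hormone_b)) {
    if (!(x %in% h)) stop("unknown hormone node: ", x)
  }
  acts <- network$edges[network$edges$relation == "acts_in", , drop = FALSE]
  nb <- function(hormone) {
    unique(c(acts$from[acts$to == hormone], acts$to[acts$from == hormone]))
  }
  sort(intersect(nb(hormone_a), nb(hormone_b)))
}

#' Summarise a network's topology
#'
#' Node counts by kind, edge count, connected components, and the number of
#' connected node pairs (the sum over components of `n*(n-1)/2`).
#'
#' @param network a [crosstalk_network()] or igraph object.
#' @return A one-row tibble.
#' @export
network_summary <- function(network) {
  g <- as_adjacency(network)
  comp <- graph_components(g)
  sizes <- as.integer(table(comp))
  kinds <- if (inherits(network, "crosstalk_network")) network$nodes$kind else
    rep("node", length(g$ids))
  tibble::tibble(
    n_nodes = length(g$ids),
    n_enzyme = sum(kinds == "enzyme"),
    n_hormone = sum(kinds == "hormone"),
    n_tf = sum(kinds == "tf"),
    n_edges = adjacency_edge_count(g),
    n_components = length(sizes),
    connected_pairs = sum(sizes * (sizes - 1) / 2)
  )
}
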