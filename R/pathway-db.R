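#' Construct a pathway database
#'
#' A `pathway_db` bundles the four entity tables of a BioCyc-style pathway
#' database: compounds, reactions, enzymes and pathways. It is the substrate
#' universe for all network construction in this package. Use
#' [parse_pathway_flatfiles()] to build one from flat-files, or
#' [generate_pathway_db()] for synthetic data.
#'
#' @param compounds tibble with columns `compound_id`, `name`, `synonyms`
#'   (list column of character vectors).
#' @param reactions tibble with columns `reaction_id`, `ec_numbers`,
#'   `substrate_ids`, `product_ids` (list columns), `reversible` (logical),
#'   `pathway_ids` (list column).
#' @param enzymes tibble with columns `enzyme_id`, `ec`, `display_name`,
#'   `gene_ids`, `protein_ids` (list columns).
#' @param pathways tibble with columns `pathway_id`, `name`.
#' @return An object of class `pathway_db`.
#' @seealso [validate_db()]
#' @export
pathway_db <- function(compounds, reactions, enzymes, pathways) {
  compounds <- tibble::as_tibble(compounds)
  reactions <- tibble::as_tibble(reactions)
  enzymes <- tibble::as_tibble(enzymes)
  pathways <- tibble::as_tibble(pathways)
  db <- structure(
    list(compounds = compounds, reactions = reactions,
         enzymes = enzymes, pathways = pathways),
    class = "pathway_db"
  )
  db
}

#' @export
print.pathway_db <- function(x, ...) {
  cat("<pathway_db> ",
      nrow(x$compounds), " compounds, ",
      nrow(x$reactions), " reactions, ",
      nrow(x$enzymes), " enzyme records (",
      length(unique(x$enzymes$ec)), " distinct EC), ",
      nrow(x$pathways), " pathways\n", sep = "")
  invisible(x)
}

#' Validate a pathway database
#'
#' Reports referential-integrity problems without throwing: dangling compound
#' or pathway references, duplicate identifiers, reactions with both sides
#' empty, and enzyme records that duplicate an EC under distinct ids
#' (a warning-level entry). An empty report means the database is valid.
#'
#' @param db a [pathway_db()].
#' @return A tibble with columns `severity` (`"error"` or `"warning"`),
#'   `type`, `record`, `detail`; zero rows when the database is clean.
#' @export
validate_db <- function(db) {
  stopifnot(inherits(db, "pathway_db"))
  rows <- list()
  add <- function(severity, type, record, detail) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      severity = severity, type = type, record = record, detail = detail)
  }
  dup_report <- function(ids, what) {
    d <- unique(ids[duplicated(ids)])
    for (id in d) add("error", "duplicate_id", id, paste0("duplicate ", what, " id"))
  }
  dup_report(db$compounds$compound_id, "compound")
  dup_report(db$reactions$reaction_id, "reaction")
  dup_report(db$enzymes$enzyme_id, "enzyme")
  dup_report(db$pathways$pathway_id, "pathway")

  cpd <- db$compounds$compound_id
  pwy <- db$pathways$pathway_id
  for (i in seq_len(nrow(db$reactions))) {
    r <- db$reactions[i, ]
    subs <- r$substrate_ids[[1]]
    prods <- r$product_ids[[1]]
    miss <- setdiff(c(subs, prods), cpd)
    if (length(miss)) {
      add("error", "dangling_compound", r$reaction_id,
          paste("unknown compound(s):", paste(sort(miss), collapse = ", ")))
    }
    mp <- setdiff(r$pathway_ids[[1]], pwy)
    if (length(mp)) {
      add("error", "dangling_pathway", r$reaction_id,
          paste("unknown pathway(s):", paste(sort(mp), collapse = ", ")))
    }
    if (length(subs) + length(prods) == 0L) {
      add("error", "empty_reaction", r$reaction_id, "no substrates and no products")
    }
    bad_ec <- r$ec_numbers[[1]][!ec_is_valid(r$ec_numbers[[1]])]
    if (length(bad_ec)) {
      add("error", "malformed_ec", r$reaction_id,
          paste("bad EC string(s):", paste(bad_ec, collapse = ", ")))
    }
  }
  if (nrow(db$enzymes)) {
    bad_ec <- db$enzymes$enzyme_id[!ec_is_valid(db$enzymes$ec)]
    for (id in bad_ec) add("error", "malformed_ec", id, "enzyme EC does not match the EC shape")
    tab <- table(db$enzymes$ec)
    for (ec in names(tab)[tab > 1L]) {
      ids <- db$enzymes$enzyme_id[db$enzymes$ec == ec]
      add("warning", "duplicate_ec", ec,
          paste("EC shared by records:", paste(sort(ids), collapse = ", ")))
    }
  }
  if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(severity = character(), type = character(),
                   record = character(), detail = character())
}

# Stop if the validation report carries error-level entries.
assert_valid_db <- function(db) {
  rep <- validate_db(db)
  errs <- rep[rep$severity == "error", , drop = FALSE]
  if (nrow(errs)) {
    stop("pathway database integrity error(s):\n",
         paste(utils::head(paste0("  [", errs$type, "] ", errs$record, ": ", errs$detail), 20L),
               collapse = "\n"))
  }
  invisible(db)
}

# --- internal indexes ------------------------------------------------------

# Collapse enzyme records by EC string: one network node per EC, genes and
# proteins pooled. Returns tibble(ec, gene_ids, protein_ids, display_name).
enzymes_by_ec <- function(db) {
  if (!nrow(db$enzymes)) {
    return(tibble::tibble(ec = character(), display_name = character(),
                          gene_ids = list(), protein_ids = list()))
  }
  db$enzymes |>
    dplyr::group_by(.data$ec) |>
    dplyr::summarise(
      display_name = dplyr::first(.data$display_name),
      gene_ids = list(sort(unique(unlist(.data$gene_ids)))),
      protein_ids = list(sort(unique(unlist(.data$protein_ids)))),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$ec)
}

# Reactions catalysed by each EC (exact membership of the reaction's EC list).
reactions_of_ec <- function(db, ec) {
  keep <- vapply(db$reactions$ec_numbers, function(e) ec %in% e, logical(1))
  db$reactions[keep, , drop = FALSE]
}

# Per-EC compound participation. Returns a list keyed by EC with elements
# substrates, products, all (character vectors; reversible reactions
# contribute both sides to both roles), and pathways.
ec_compound_index <- function(db, ecs = NULL) {
  enz <- enzymes_by_ec(db)
  if (is.null(ecs)) ecs <- enz$ec
  rx <- db$reactions
  out <- lapply(ecs, function(ec) {
    keep <- vapply(rx$ec_numbers, function(e) ec %in% e, logical(1))
    subs <- character(); prods <- character(); pwys <- character()
    if (any(keep)) {
      r <- rx[keep, , drop = FALSE]
      for (i in seq_len(nrow(r))) {
        s <- r$substrate_ids[[i]]; p <- r$product_ids[[i]]
        if (isTRUE(r$reversible[i])) { s2 <- union(s, p); p <- s2; s <- s2 }
        subs <- c(subs, s); prods <- c(prods, p)
      }
      pwys <- unlist(r$pathway_ids)
    }
    list(substrates = sort(unique(subs)), products = sort(unique(prods)),
         all = sort(unique(c(subs, prods))), pathways = sort(unique(pwys)))
  })
  names(out) <- ecs
  out
}
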