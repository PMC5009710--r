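#' Overlay transcript and protein evidence on a metabolic route
#'
#' For each route step the enzyme-encoding genes are collected from the
#' database by EC matching (a family-level EC such as `2.4.1.-` aggregates the
#' genes of every matching enzyme record), then intersected with the
#' expressed-gene and detected-protein lists. Regulating TFs are the TFs whose
#' targets intersect the step's genes, restricted to the expressed set.
#'
#' @param route a `metabolic_route` from [extract_routes()].
#' @param db a [pathway_db()].
#' @param regulation tibble from [parse_regulation_table()].
#' @param evidence an `evidence_sets` record from [parse_expression_lists()].
#' @param annotations tibble from [parse_hormone_annotations()].
#' @return A tibble of class `evidence_report`: `step`, `ec`, `gene_ids`,
#'   `expressed_gene_ids`, `protein_supported_gene_ids`,
#'   `expressed_regulating_tfs`, `hormones` (list columns).
#' @export
annotate_evidence <- function(route, db, regulation, evidence, annotations) {
  stopifnot(inherits(route, "metabolic_route"), inherits(db, "pathway_db"),
            inherits(evidence, "evidence_sets"))
  enz <- enzymes_by_ec(db)
  base <- route_report(route, db, annotations)
  expressed <- evidence$expressed_gene_ids
  proteins <- evidence$detected_protein_gene_ids
  regulation <- tibble::as_tibble(regulation)
  rows <- lapply(seq_along(route$steps), function(i) {
    step_ec <- route$steps[i]
    hits <- enz$ec[ec_match(enz$ec, step_ec)]
    genes <- sort(unique(unlist(enz$gene_ids[enz$ec %in% hits])))
    tfs <- sort(unique(regulation$tf_gene_id[regulation$target_gene_id %in% genes]))
    tibble::tibble(
      step = i, ec = step_ec,
      gene_ids = list(genes),
      expressed_gene_ids = list(intersect(genes, expressed)),
      protein_supported_gene_ids = list(intersect(genes, proteins)),
      expressed_regulating_tfs = list(intersect(tfs, expressed)),
      hormones = base$hormones[i])
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("evidence_report", class(out))
  out
}

#' Summarise evidence coverage of a route
#'
#' @param report an `evidence_report` from [annotate_evidence()].
#' @return A one-row tibble: `steps_total`, `steps_with_transcript`,
#'   `steps_with_protein`, `fraction_transcript`, `fraction_protein`.
#' @export
coverage_summary <- function(report) {
  if (!nrow(report)) stop("evidence report is empty")
  n <- nrow(report)
  wt <- sum(lengths(report$expressed_gene_ids) > 0L)
  wp <- sum(lengths(report$protein_supported_gene_ids) > 0L)
  tibble::tibble(
    steps_total = n,
    steps_with_transcript = wt,
    steps_with_protein = wp,
    fraction_transcript = wt / n,
    fraction_protein = wp / n)
}

#' Permutation support for a route's transcript coverage
#'
#' Null model: random enzyme sets of the route's size are drawn from the
#' database's enzymes and scored by the same transcript-coverage fraction.
#' The p-value is `(1 + #{permutation coverage >= observed}) / (n_perm + 1)`.
#'
#' @inheritParams annotate_evidence
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed; fixed seed gives identical p-values across runs.
#' @return A one-row tibble: `observed_coverage`, `n_perm`, `p_value`.
#' @export
permutation_support <- function(route, db, evidence, n_perm = 999L, seed = 1L) {
  stopifnot(inherits(route, "metabolic_route"), inherits(db, "pathway_db"))
  if (n_perm < 100L) stop("n_perm must be >= 100")
  enz <- enzymes_by_ec(db)
  k <- length(route$steps)
  if (k > nrow(enz)) stop("route is larger than the enzyme universe")
  expressed <- evidence$expressed_gene_ids
  # precompute, per candidate EC pattern, whether its aggregated genes carry
  # transcript evidence (wildcard patterns pool all matching enzyme records)
  patterns <- unique(c(route$steps, enz$ec))
  has_transcript <- vapply(patterns, function(p) {
    genes <- unlist(enz$gene_ids[ec_match(enz$ec, p)])
    length(intersect(genes, expressed)) > 0L
  }, logical(1))
  names(has_transcript) <- patterns
  cover_fraction <- function(ecs) mean(has_transcript[ecs])
  observed <- cover_fraction(route$steps)
  count <- 0L
  withr::with_seed(seed, {
    for (r in seq_len(n_perm)) {
      draw <- sample(enz$ec, k)
      if (cover_fraction(draw) >= observed - 1e-12) count <- count + 1L
    }
  })
  tibble::tibble(observed_coverage = observed, n_perm = as.integer(n_perm),
                 p_value = (1 + count) / (n_perm + 1))
}
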