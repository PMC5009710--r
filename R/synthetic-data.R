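#' Parameters for synthetic pathway, regulation and evidence data
#'
#' The defaults mirror the structure of the packaged crosstalk analysis: a
#' planted 13-step producer/consumer route, eleven enzymes bridging the auxin
#' and cytokinin pathway sets, all eight hormones annotated, a planted 6-TF
#' co-target cycle with a PPI chain over its members, and presence/absence
#' evidence with 90% sensitivity and a 5% false-positive rate.
#'
#' @param seed integer seed governing every random choice.
#' @param n_compounds background (non-currency, non-linker) compound count.
#' @param n_currency currency compounds emitted (ids `CUR-1`...).
#' @param n_pathways background pathway count (hormone pathways are extra).
#' @param reactions_per_pathway background reactions per background pathway.
#' @param n_enzymes background enzyme count.
#' @param planted_route_length length of the planted enzyme route.
#' @param n_hormones number of hormones annotated (up to 8).
#' @param hormone_bridge_enzymes named integer vector; names are
#'   `"hormoneA:hormoneB"` pairs, values the number of enzymes planted in
#'   pathways of both hormones.
#' @param n_tfs,n_targets TF and target universe sizes for regulation data.
#' @param planted_cycle_lengths lengths (each >= 3) of planted co-target
#'   cycles.
#' @param background_cotarget_density probability that a random TF pair
#'   shares a background target.
#' @param evidence_sensitivity probability a truly expressed gene appears in
#'   the expressed list.
#' @param evidence_false_positive_rate probability a non-expressed gene
#'   appears anyway.
#' @return A list of class `synthesis_params`.
#' @export
synthesis_params <- function(seed = 1L,
                             n_compounds = 60L,
                             n_currency = 6L,
                             n_pathways = 10L,
                             reactions_per_pathway = 4L,
                             n_enzymes = 30L,
                             planted_route_length = 13L,
                             n_hormones = 8L,
                             hormone_bridge_enzymes = c("auxin:cytokinin" = 11L),
                             n_tfs = 30L,
                             n_targets = 40L,
                             planted_cycle_lengths = 6L,
                             background_cotarget_density = 0.02,
                             evidence_sensitivity = 0.9,
                             evidence_false_positive_rate = 0.05) {
  stopifnot(n_compounds > 0, n_currency > 0, n_pathways > 0,
            reactions_per_pathway > 0, n_enzymes > 0,
            planted_route_length >= 1, n_hormones >= 1, n_hormones <= 8,
            n_tfs > 0, n_targets > 0,
            background_cotarget_density >= 0, background_cotarget_density <= 1,
            evidence_sensitivity >= 0, evidence_sensitivity <= 1,
            evidence_false_positive_rate >= 0, evidence_false_positive_rate <= 1)
  if (any(planted_cycle_lengths < 3L)) stop("planted cycle lengths must be >= 3")
  structure(as.list(environment()), class = "synthesis_params")
}

syn_locus <- function(prefix, i) sprintf("ZZ%dG%05d", prefix, i)

#' Generate a synthetic pathway database with planted structures
#'
#' Emits a [pathway_db()] plus hormone annotations and a ground-truth record.
#' The database contains a planted producer/consumer chain of
#' `planted_route_length` enzymes linked through unique non-currency
#' compounds, the requested number of hormone-bridging enzymes per hormone
#' pair (each catalysing one reaction assigned to a pathway of each hormone),
#' and random background reactions that cannot touch the planted chain
#' (background reactions draw from a disjoint compound pool). The planted
#' route's recovery by the exact route extractor is checked before returning.
#' With `dir` set, flat-files and the annotation table are written
#' deterministically (fixed seed, byte-identical output).
#'
#' @param params a [synthesis_params()].
#' @param dir optional output directory for flat-files.
#' @return A list `db`, `annotations`, `truth` (class `ground_truth`:
#'   `route_enzymes`, `route_links`, `bridge_enzymes`, `expressed_genes`).
#' @export
generate_pathway_db <- function(params = synthesis_params(), dir = NULL) {
  stopifnot(inherits(params, "synthesis_params"))
  L <- params$planted_route_length
  if (L > params$n_enzymes + L) stop("infeasible: route longer than enzyme universe")
  hormones <- hormone_vocabulary()[seq_len(params$n_hormones)]
  for (pair in names(params$hormone_bridge_enzymes)) {
    hs <- strsplit(pair, ":", fixed = TRUE)[[1]]
    if (length(hs) != 2L || !all(hs %in% hormones)) {
      stop("bridge pair must name two annotated hormones: ", pair)
    }
  }

  withr::with_seed(params$seed, {
    currency <- sprintf("CUR-%d", seq_len(params$n_currency))
    background_cpd <- sprintf("CPD-%04d", seq_len(params$n_compounds))
    linkers <- sprintf("LINK-%02d", seq_len(max(L - 1L, 0L)))
    route_aux <- c(sprintf("RSUB-%02d", seq_len(L)), sprintf("RPROD-%02d", seq_len(L)))

    hormone_pwy <- sprintf("PWY-%s", toupper(gsub(" ", "-", hormones)))
    names(hormone_pwy) <- hormones
    background_pwy <- sprintf("PWY-BG-%03d", seq_len(params$n_pathways))

    route_ec <- sprintf("9.9.9.%d", seq_len(L))
    route_genes <- syn_locus(1, seq_len(L))
    route_rx <- lapply(seq_len(L), function(i) {
      subs <- c(if (i > 1L) linkers[i - 1L], sprintf("RSUB-%02d", i), currency[1])
      prods <- c(if (i < L) linkers[i], sprintf("RPROD-%02d", i))
      tibble::tibble(
        reaction_id = sprintf("RXN-ROUTE-%02d", i),
        ec_numbers = list(route_ec[i]),
        substrate_ids = list(sort(subs)), product_ids = list(sort(prods)),
        reversible = FALSE,
        pathway_ids = list(hormone_pwy[[hormones[((i - 1L) %% length(hormones)) + 1L]]]))
    })

    bridge_rows <- list(); bridge_truth <- list(); bi <- 0L
    for (pair in names(params$hormone_bridge_enzymes)) {
      hs <- strsplit(pair, ":", fixed = TRUE)[[1]]
      cnt <- params$hormone_bridge_enzymes[[pair]]
      ecs <- character(cnt)
      for (j in seq_len(cnt)) {
        bi <- bi + 1L
        ecs[j] <- sprintf("8.8.%d.%d", match(pair, names(params$hormone_bridge_enzymes)), j)
        bridge_rows[[bi]] <- tibble::tibble(
          reaction_id = sprintf("RXN-BRIDGE-%03d", bi),
          ec_numbers = list(ecs[j]),
          substrate_ids = list(sprintf("BSUB-%03d", bi)),
          product_ids = list(sprintf("BPROD-%03d", bi)),
          reversible = FALSE,
          pathway_ids = list(sort(unname(hormone_pwy[hs]))))
      }
      bridge_truth[[pair]] <- sort(ecs)
    }
    bridge_cpd <- c(sprintf("BSUB-%03d", seq_len(bi)), sprintf("BPROD-%03d", seq_len(bi)))

    bg_ec <- sprintf("7.7.%d.%d", rep(seq_len(ceiling(params$n_enzymes / 10)), each = 10)[seq_len(params$n_enzymes)],
                     rep(1:10, length.out = params$n_enzymes))
    bg_rx <- list(); ri <- 0L
    for (p in background_pwy) {
      for (r in seq_len(params$reactions_per_pathway)) {
        ri <- ri + 1L
        ns <- sample(1:3, 1); np <- sample(1:3, 1)
        cpds <- sample(background_cpd, ns + np)
        bg_rx[[ri]] <- tibble::tibble(
          reaction_id = sprintf("RXN-BG-%04d", ri),
          ec_numbers = list(sort(sample(bg_ec, sample(1:2, 1)))),
          substrate_ids = list(sort(cpds[seq_len(ns)])),
          product_ids = list(sort(cpds[ns + seq_len(np)])),
          reversible = stats::runif(1) < 0.2,
          pathway_ids = list(p))
      }
    }

    compounds <- tibble::tibble(
      compound_id = c(currency, background_cpd, linkers, route_aux, bridge_cpd),
      name = tolower(c(currency, background_cpd, linkers, route_aux, bridge_cpd)),
      synonyms = rep(list(character()), params$n_currency + params$n_compounds +
                       length(linkers) + length(route_aux) + length(bridge_cpd)))
    reactions <- dplyr::bind_rows(c(route_rx, bridge_rows, bg_rx))
    enzymes <- tibble::tibble(
      enzyme_id = c(route_ec, unlist(unname(bridge_truth)), unique(bg_ec)),
      ec = c(route_ec, unlist(unname(bridge_truth)), unique(bg_ec)))
    enzymes$display_name <- paste("enzyme", enzymes$ec)
    enzymes$gene_ids <- c(as.list(route_genes),
                          rep(list(character()), nrow(enzymes) - L))
    enzymes$gene_ids[L + seq_along(unlist(bridge_truth))] <-
      as.list(syn_locus(2, seq_along(unlist(bridge_truth))))
    enzymes$protein_ids <- rep(list(character()), nrow(enzymes))
    pathways <- tibble::tibble(
      pathway_id = c(unname(hormone_pwy), background_pwy),
      name = c(paste(hormones, "pathway"), paste("background pathway", seq_along(background_pwy))))

    annotations <- tibble::tibble(
      hormone = hormones, pathway_id = unname(hormone_pwy),
      role = rep(annotation_roles(), length.out = length(hormones)))

    db <- pathway_db(compounds, reactions, enzymes, pathways)
  })
  assert_valid_db(db)

  truth <- structure(list(
    route_enzymes = route_ec <- sprintf("9.9.9.%d", seq_len(L)),
    route_links = if (L > 1L) sprintf("LINK-%02d", seq_len(L - 1L)) else character(),
    bridge_enzymes = bridge_truth,
    expressed_genes = syn_locus(1, seq_len(L))), class = "ground_truth")

  # planted-route recovery check with the exact extractor
  cg <- build_coupling_graph(db, truth$route_enzymes,
                             currency_policy(sprintf("CUR-%d", seq_len(params$n_currency))))
  routes <- extract_routes(cg)
  ok <- length(routes) == 1L && identical(routes[[1]]$steps, truth$route_enzymes)
  if (!ok) stop("internal error: planted route not uniquely recoverable")

  if (!is.null(dir)) {
    write_pathway_flatfiles(db, dir)
    readr::write_lines(
      c("hormone\tpathway_id\trole",
        paste(annotations$hormone, annotations$pathway_id, annotations$role, sep = "\t")),
      file.path(dir, "hormone_annotations.tsv"))
  }
  list(db = db, annotations = annotations, truth = truth)
}

#' Generate synthetic TF regulation and PPI tables with planted cycles
#'
#' Each planted cycle of length `k` gets `k` TFs; consecutive TFs (with
#' wrap-around) share one dedicated target gene, so the induced co-target
#' graph contains exactly that cycle. Background co-targeting adds, for each
#' random TF pair selected at `background_cotarget_density`, one fresh shared
#' target. PPI pairs form a chain over each planted cycle's TFs in cycle
#' order.
#'
#' @param params a [synthesis_params()].
#' @param dir optional output directory (`regulation.tsv`, `ppi.tsv`).
#' @return A list `regulation`, `ppi`, `truth` (fields `cycles`: list of TF
#'   id vectors, `ppi_chains`).
#' @export
generate_regulation <- function(params = synthesis_params(), dir = NULL) {
  stopifnot(inherits(params, "synthesis_params"))
  if (any(params$planted_cycle_lengths < 3L)) stop("cycle length must be >= 3")
  withr::with_seed(params$seed + 1L, {
    total_planted <- sum(params$planted_cycle_lengths)
    n_tfs <- max(params$n_tfs, total_planted)
    tfs <- syn_locus(5, seq_len(n_tfs))
    rows <- list(); cycles <- list(); chains <- list(); ti <- 0L; gi <- 0L
    for (ci in seq_along(params$planted_cycle_lengths)) {
      k <- params$planted_cycle_lengths[ci]
      members <- tfs[ti + seq_len(k)]; ti <- ti + k
      for (j in seq_len(k)) {
        gi <- gi + 1L
        target <- syn_locus(6, gi)
        a <- members[j]; b <- members[(j %% k) + 1L]
        rows[[length(rows) + 1L]] <- tibble::tibble(
          tf_gene_id = c(a, b), target_gene_id = target)
      }
      cycles[[ci]] <- members
      chains[[ci]] <- members
    }
    # background co-targeting among all TFs
    others <- tfs
    if (length(others) >= 2L && params$background_cotarget_density > 0) {
      for (i in seq_len(length(others) - 1L)) {
        for (j in (i + 1L):length(others)) {
          if (stats::runif(1) < params$background_cotarget_density) {
            gi <- gi + 1L
            rows[[length(rows) + 1L]] <- tibble::tibble(
              tf_gene_id = c(others[i], others[j]),
              target_gene_id = syn_locus(6, gi))
          }
        }
      }
    }
    regulation <- if (length(rows)) dplyr::bind_rows(rows) else
      tibble::tibble(tf_gene_id = character(), target_gene_id = character())
    regulation <- dplyr::arrange(dplyr::distinct(regulation),
                                 .data$tf_gene_id, .data$target_gene_id)
    ppi <- dplyr::bind_rows(lapply(chains, function(m) {
      if (length(m) < 2L) return(NULL)
      tibble::tibble(gene_a = pmin(m[-length(m)], m[-1]),
                     gene_b = pmax(m[-length(m)], m[-1]))
    }))
    if (is.null(ppi) || !nrow(ppi)) {
      ppi <- tibble::tibble(gene_a = character(), gene_b = character())
    }
    ppi <- dplyr::arrange(dplyr::distinct(ppi), .data$gene_a, .data$gene_b)
  })
  truth <- structure(list(cycles = cycles, ppi_chains = chains), class = "ground_truth")
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    readr::write_lines(
      c("tf_gene_id\ttarget_gene_id",
        paste(regulation$tf_gene_id, regulation$target_gene_id, sep = "\t")),
      file.path(dir, "regulation.tsv"))
    readr::write_lines(
      c("gene_a\tgene_b", paste(ppi$gene_a, ppi$gene_b, sep = "\t")),
      file.path(dir, "ppi.tsv"))
  }
  list(regulation = regulation, ppi = ppi, truth = truth)
}

#' Generate noisy expression evidence from a ground truth
#'
#' Each truly expressed gene enters the expressed list with probability
#' `evidence_sensitivity`; each other gene of `universe` enters with
#' probability `evidence_false_positive_rate`. The protein list is drawn the
#' same way from the truly expressed set.
#'
#' @param truth a `ground_truth` with an `expressed_genes` field.
#' @param params a [synthesis_params()].
#' @param universe all candidate gene ids (defaults to the truth set).
#' @return An `evidence_sets` record.
#' @export
generate_evidence <- function(truth, params = synthesis_params(),
                              universe = NULL) {
  stopifnot(inherits(params, "synthesis_params"))
  true_set <- truth$expressed_genes
  if (is.null(universe)) universe <- true_set
  universe <- sort(unique(union(universe, true_set)))
  withr::with_seed(params$seed + 2L, {
    keep_true <- true_set[stats::runif(length(true_set)) < params$evidence_sensitivity]
    rest <- setdiff(universe, true_set)
    keep_fp <- rest[stats::runif(length(rest)) < params$evidence_false_positive_rate]
    proteins <- true_set[stats::runif(length(true_set)) < params$evidence_sensitivity]
  })
  structure(list(expressed_gene_ids = sort(unique(c(keep_true, keep_fp))),
                 detected_protein_gene_ids = sort(unique(proteins)),
                 context = "synthetic"),
            class = "evidence_sets")
}
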