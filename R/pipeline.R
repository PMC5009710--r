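#' Run the full crosstalk analysis pipeline
#'
#' Executes every stage end to end: parse inputs, build the GECN and EAPCN,
#' compute the twelve-index centrality table, select hubs, detect cohesive
#' clusters, build the coupling graph over the route enzyme set, extract
#' routes, build the TF co-target network, enumerate cycles and control
#' units, and overlay expression evidence. All intermediate artifacts are
#' written as TSV/SIF/GraphML under `out_dir`; every header records the seed,
#' and rerunning with the same config and seed reproduces the outputs byte
#' for byte.
#'
#' @param config a named list or the path to a YAML file with entries:
#'   `use_fixture` (logical; use the packaged fixture) or paths `db_dir`
#'   (flat-file directory), `annotations`, `regulation`, `ppi`,
#'   `expressed_genes`, `detected_proteins`; optional `route_enzymes`
#'   (file with one EC per line, overrides hub selection), `currency`
#'   (file with one compound id per line), `hub_k`, `hub_m`, `max_cycle_len`,
#'   `seed`, `out_dir`.
#' @return A one-row summary tibble (also written to `summary.tsv`),
#'   invisibly the full result bundle as attribute `"results"`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  cfg <- utils::modifyList(
    list(use_fixture = FALSE, hub_k = 10L, hub_m = 6L, max_cycle_len = 15L,
         seed = 1L, out_dir = tempfile("hormonet-run-")),
    config)
  out <- cfg$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  seed <- as.integer(cfg$seed)
  stage <- function(name, expr) {
    message("[hormonet] stage: ", name)
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  inputs <- stage("parse", {
    if (isTRUE(cfg$use_fixture)) {
      load_crosstalk_fixture()
    } else {
      list(
        db = parse_pathway_flatfiles(
          file.path(cfg$db_dir, "compounds.dat"), file.path(cfg$db_dir, "reactions.dat"),
          file.path(cfg$db_dir, "enzymes.dat"), file.path(cfg$db_dir, "pathways.dat")),
        annotations = parse_hormone_annotations(cfg$annotations),
        regulation = parse_regulation_table(cfg$regulation),
        ppi = parse_ppi_table(cfg$ppi),
        evidence = parse_expression_lists(cfg$expressed_genes, cfg$detected_proteins),
        route_enzymes = if (!is.null(cfg$route_enzymes)) {
          x <- trimws(readr::read_lines(cfg$route_enzymes))
          x[nzchar(x) & !startsWith(x, "#")]
        })
    }
  })
  policy <- if (!is.null(cfg$currency)) {
    x <- trimws(readr::read_lines(cfg$currency))
    currency_policy(x[nzchar(x) & !startsWith(x, "#")])
  } else currency_policy()

  hdr <- function(file) readr::write_lines(paste0("# seed: ", seed), file)
  tsv_with_header <- function(tab, file) {
    hdr(file)
    readr::write_lines(paste(names(tab), collapse = "\t"), file, append = TRUE)
    if (nrow(tab)) {
      flat <- vapply(seq_len(nrow(tab)), function(i) {
        paste(vapply(tab[i, ], function(col) {
          v <- col[[1]]
          if (is.list(v)) v <- unlist(v)
          paste(format(v, trim = TRUE, scientific = FALSE), collapse = "|")
        }, character(1)), collapse = "\t")
      }, character(1))
      readr::write_lines(flat, file, append = TRUE)
    }
  }

  gecn <- stage("gecn", build_gecn(inputs$db, policy))
  write_network(gecn, file.path(out, "gecn.sif"), "sif")
  eapcn <- stage("eapcn", build_eapcn(inputs$db, inputs$annotations, policy))
  write_network(eapcn, file.path(out, "eapcn.graphml"), "graphml")
  write_network(eapcn, file.path(out, "eapcn.tsv"), "tsv")

  enzyme_sub <- crosstalk_network(
    eapcn$nodes[eapcn$nodes$kind == "enzyme", , drop = FALSE],
    eapcn$edges[eapcn$edges$relation == "shares_compound", , drop = FALSE],
    type = "eapcn_enzymes")
  cent <- stage("centrality",
                compute_centrality(enzyme_sub, centrality_params(epc_seed = seed)))
  tsv_with_header(cent, file.path(out, "centrality.tsv"))
  hubs <- stage("hubs", rank_and_select_hubs(cent, k = cfg$hub_k, m = cfg$hub_m))
  hdr(file.path(out, "hubs.txt"))
  readr::write_lines(hubs, file.path(out, "hubs.txt"), append = TRUE)

  clusters <- stage("clusters", detect_clusters(enzyme_sub))
  tsv_with_header(clusters, file.path(out, "clusters.tsv"))

  route_set <- if (!is.null(inputs$route_enzymes)) inputs$route_enzymes else hubs
  routes <- list()
  if (length(route_set)) {
    coupling <- stage("coupling", build_coupling_graph(inputs$db, route_set, policy))
    write_network(coupling, file.path(out, "coupling.tsv"), "tsv")
    routes <- stage("routes", extract_routes(coupling))
    route_tab <- dplyr::bind_rows(lapply(seq_along(routes), function(i) {
      tibble::tibble(route = i, step = seq_along(routes[[i]]$steps),
                     ec = routes[[i]]$steps,
                     link_to_next = c(routes[[i]]$links, NA_character_))
    }))
    tsv_with_header(route_tab, file.path(out, "routes.tsv"))
  }

  enzyme_genes <- sort(unique(unlist(
    enzymes_by_ec(inputs$db)$gene_ids[enzymes_by_ec(inputs$db)$ec %in%
                                        eapcn$nodes$id[eapcn$nodes$kind == "enzyme"]])))
  tfnet <- stage("tf_network", build_cotarget_network(inputs$regulation))
  write_network(tfnet, file.path(out, "tf_network.tsv"), "tsv")
  cycles <- stage("cycles", enumerate_cycles(tfnet, max_len = cfg$max_cycle_len))
  units <- stage("units", assemble_units(cycles, tfnet, enzyme_genes))
  unit_tab <- dplyr::bind_rows(lapply(seq_along(units), function(i) {
    tibble::tibble(unit = i, n_tfs = length(units[[i]]$members),
                   n_cycles = length(units[[i]]$cycles),
                   members = paste(units[[i]]$members, collapse = "|"),
                   regulated_enzyme_genes = paste(units[[i]]$regulated_enzyme_genes, collapse = "|"))
  }))
  if (!nrow(unit_tab)) unit_tab <- tibble::tibble(unit = integer(), n_tfs = integer(),
                                                  n_cycles = integer(), members = character(),
                                                  regulated_enzyme_genes = character())
  tsv_with_header(unit_tab, file.path(out, "units.tsv"))

  evid <- NULL
  if (length(routes)) {
    evid <- stage("evidence", annotate_evidence(
      routes[[1]], inputs$db, inputs$regulation, inputs$evidence, inputs$annotations))
    tsv_with_header(evid, file.path(out, "evidence.tsv"))
  }

  summary_tab <- tibble::tibble(
    seed = seed,
    n_hormone_nodes = sum(eapcn$nodes$kind == "hormone"),
    n_eapcn_enzymes = sum(eapcn$nodes$kind == "enzyme"),
    n_gecn_edges = nrow(gecn$edges),
    n_hubs = length(hubs),
    n_clusters = nrow(clusters),
    n_routes = length(routes),
    max_route_steps = if (length(routes)) length(routes[[1]]$steps) else 0L,
    n_tf_cycles = length(cycles),
    n_control_units = length(units),
    steps_with_transcript = if (!is.null(evid)) coverage_summary(evid)$steps_with_transcript else NA_integer_)
  tsv_with_header(summary_tab, file.path(out, "summary.tsv"))
  attr(summary_tab, "results") <- list(
    gecn = gecn, eapcn = eapcn, centrality = cent, hubs = hubs,
    clusters = clusters, routes = routes, tf_network = tfnet,
    cycles = cycles, units = units, evidence = evid, out_dir = out)
  summary_tab
}
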