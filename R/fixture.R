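#' Load the packaged crosstalk fixture
#'
#' Returns the curated demonstration dataset shipped with the package: a
#' pathway database covering the 13-step consecutive metabolic route and the
#' eleven auxin-cytokinin bridge enzymes, hormone annotations for all eight
#' hormones, TF regulation rows forming the circular control units, the
#' protein-interaction chain of unit C, and root-stele expression evidence.
#' See `inst/extdata/fixture/README.md` for curation notes (synthetic
#' placeholder compounds and reactions carry a `SYNTHETIC-` prefix).
#'
#' @return A list with elements `db` ([pathway_db()]), `annotations`,
#'   `regulation`, `ppi`, `evidence` (`evidence_sets`), and `route_enzymes`
#'   (the route's 13 EC ids in step order).
#' @examples
#' fx <- load_crosstalk_fixture()
#' length(fx$route_enzymes)
#' @export
load_crosstalk_fixture <- function() {
  dir <- system.file("extdata", "fixture", package = "hormonet", mustWork = TRUE)
  db <- parse_pathway_flatfiles(
    file.path(dir, "compounds.dat"), file.path(dir, "reactions.dat"),
    file.path(dir, "enzymes.dat"), file.path(dir, "pathways.dat"))
  annotations <- parse_hormone_annotations(file.path(dir, "hormone_annotations.tsv"))
  regulation <- parse_regulation_table(file.path(dir, "regulation.tsv"))
  ppi <- parse_ppi_table(file.path(dir, "ppi.tsv"))
  evidence <- parse_expression_lists(
    file.path(dir, "expressed_genes.txt"), file.path(dir, "detected_proteins.txt"),
    context = "root stele (vasculature)")
  route_lines <- readr::read_lines(file.path(dir, "route_enzymes.txt"))
  route_enzymes <- trimws(route_lines)
  route_enzymes <- route_enzymes[nzchar(route_enzymes) & !startsWith(route_enzymes, "#")]
  list(db = db, annotations = annotations, regulation = regulation,
       ppi = ppi, evidence = evidence, route_enzymes = route_enzymes)
}
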