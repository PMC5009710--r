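#' The eight phytohormones and annotation roles
#'
#' Closed vocabularies used by hormone-to-pathway annotations.
#' @name vocabularies
#' @export
hormone_vocabulary <- function() {
  c("abscisic acid", "auxin", "brassinosteroid", "cytokinin",
    "ethylene", "gibberellin", "jasmonic acid", "salicylic acid")
}

#' @rdname vocabularies
#' @export
annotation_roles <- function() {
  c("biosynthesis", "inactivation", "degradation", "conjugation")
}

#' Read hormone-to-pathway annotations
#'
#' Expects a tab-separated table with header columns `hormone`, `pathway_id`,
#' `role`. Hormones outside the eight-element vocabulary (see
#' [hormone_vocabulary()]) and roles outside [annotation_roles()] are errors.
#' Pathway resolution is checked later, by [build_eapcn()] against a database,
#' not at parse time.
#'
#' @param file path or (with `as_lines = TRUE`) character vector of lines.
#' @param as_lines interpret `file` as lines.
#' @return A tibble with columns `hormone`, `pathway_id`, `role`.
#' @export
parse_hormone_annotations <- function(file, as_lines = FALSE) {
  lines <- if (as_lines) file else readr::read_lines(file)
  tab <- readr::read_tsv(I(paste(lines, collapse = "\n")),
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("hormone", "pathway_id", "role")
  if (!all(need %in% names(tab))) {
    stop("annotation table must have columns: ", paste(need, collapse = ", "))
  }
  tab <- dplyr::mutate(tab[need], dplyr::across(dplyr::everything(), trimws))
  bad_h <- setdiff(unique(tab$hormone), hormone_vocabulary())
  if (length(bad_h)) {
    stop("unknown hormone(s) outside the eight-element vocabulary: ",
         paste(bad_h, collapse = ", "))
  }
  bad_r <- setdiff(unique(tab$role), annotation_roles())
  if (length(bad_r)) stop("unknown annotation role(s): ", paste(bad_r, collapse = ", "))
  dplyr::distinct(tab)
}

#' Read TF regulation, protein interaction, and evidence-list tables
#'
#' `parse_regulation_table()` reads two tab-separated columns
#' (`tf_gene_id`, `target_gene_id`; a header naming them is optional) and
#' collapses duplicates. `parse_ppi_table()` reads unordered gene pairs,
#' normalizes each pair so the smaller id comes first, drops self-pairs and
#' duplicates. `parse_expression_lists()` reads one-id-per-line expressed-gene
#' and detected-protein lists into an evidence-set record. Empty inputs yield
#' empty collections with a warning.
#'
#' @param file path or (with `as_lines = TRUE`) character vector of lines.
#' @param as_lines interpret `file` as lines.
#' @return `parse_regulation_table()`: tibble `tf_gene_id`, `target_gene_id`;
#'   `parse_ppi_table()`: tibble `gene_a`, `gene_b`;
#'   `parse_expression_lists()`: a list with `expressed_gene_ids`,
#'   `detected_protein_gene_ids`, `context` (class `evidence_sets`).
#' @export
parse_regulation_table <- function(file, as_lines = FALSE) {
  tab <- read_two_columns(file, as_lines, c("tf_gene_id", "target_gene_id"))
  if (!nrow(tab)) {
    warning("regulation table is empty")
    return(tab)
  }
  if (any(!nzchar(tab$tf_gene_id)) || any(!nzchar(tab$target_gene_id))) {
    stop("regulation table contains empty identifiers")
  }
  dplyr::arrange(dplyr::distinct(tab), .data$tf_gene_id, .data$target_gene_id)
}

#' @rdname parse_regulation_table
#' @export
parse_ppi_table <- function(file, as_lines = FALSE) {
  tab <- read_two_columns(file, as_lines, c("gene_a", "gene_b"))
  if (!nrow(tab)) {
    warning("PPI table is empty")
    return(tab)
  }
  tab <- tab[tab$gene_a != tab$gene_b, , drop = FALSE]
  swap <- tab$gene_b < tab$gene_a
  tmp <- tab$gene_a[swap]; tab$gene_a[swap] <- tab$gene_b[swap]; tab$gene_b[swap] <- tmp
  dplyr::arrange(dplyr::distinct(tab), .data$gene_a, .data$gene_b)
}

#' @param gene_file,protein_file paths or line vectors of locus ids, one per
#'   line; `#` comment lines are skipped.
#' @param context free-text label for the tissue/condition the lists describe.
#' @rdname parse_regulation_table
#' @export
parse_expression_lists <- function(gene_file, protein_file, context = "",
                                   as_lines = FALSE) {
  read_ids <- function(x, what) {
    lines <- if (as_lines) x else readr::read_lines(x)
    ids <- trimws(lines)
    ids <- ids[nzchar(ids) & !startsWith(ids, "#")]
    if (!length(ids)) warning(what, " list is empty")
    sort(unique(ids))
  }
  structure(
    list(expressed_gene_ids = read_ids(gene_file, "expressed gene"),
         detected_protein_gene_ids = read_ids(protein_file, "detected protein"),
         context = context),
    class = "evidence_sets"
  )
}

read_two_columns <- function(file, as_lines, col_names) {
  lines <- if (as_lines) file else readr::read_lines(file)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  # drop a header row naming the expected columns
  if (length(lines) && identical(tolower(strsplit(lines[[1]], "\t")[[1]][1:2]),
                                 tolower(col_names))) {
    lines <- lines[-1]
  }
  if (!length(lines)) {
    out <- tibble::tibble(a = character(), b = character())
    names(out) <- col_names
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(vapply(parts, length, integer(1)) < 2L)) {
    stop("expected two tab-separated columns")
  }
  out <- tibble::tibble(a = trimws(vapply(parts, `[[`, character(1), 1L)),
                        b = trimws(vapply(parts, `[[`, character(1), 2L)))
  names(out) <- col_names
  out
}
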