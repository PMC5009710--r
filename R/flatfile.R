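# BioCyc-style attribute-value flat-file dialect:
#   one "ATTRIBUTE - VALUE" pair per line, "//" terminates a record,
#   lines beginning "/" continue the previous value, "#" starts a comment.

# Parse one stream into a list of records; each record is a list of
# character vectors keyed by attribute (repeated attributes accumulate).
parse_attr_value <- function(lines, what = "flat-file") {
  records <- list()
  current <- list()
  last_attr <- NULL
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(trimws(line))) next
    if (startsWith(line, "#")) next
    if (trimws(line) == "//") {
      if (length(current)) records[[length(records) + 1L]] <- current
      current <- list(); last_attr <- NULL
      next
    }
    if (startsWith(line, "/")) {
      if (is.null(last_attr)) {
        stop(sprintf("%s parse error at line %d: continuation line with no preceding attribute", what, i))
      }
      v <- current[[last_attr]]
      v[length(v)] <- trimws(paste(v[length(v)], trimws(sub("^/", "", line))))
      current[[last_attr]] <- v
      next
    }
    sep <- regexpr(" - ", line, fixed = TRUE)
    if (sep < 0L) {
      stop(sprintf("%s parse error at line %d: no ' - ' separator in %s", what, i, sQuote(line)))
    }
    attr <- trimws(substr(line, 1L, sep - 1L))
    value <- trimws(substr(line, sep + 3L, nchar(line)))
    current[[attr]] <- c(current[[attr]], value)
    last_attr <- attr
  }
  if (length(current)) records[[length(records) + 1L]] <- current
  records
}

rec_field <- function(rec, attr, default = character()) {
  v <- rec[[attr]]
  if (is.null(v)) default else v
}

rec_one <- function(rec, attr, default = NA_character_) {
  v <- rec[[attr]]
  if (is.null(v) || !length(v)) default else v[[1]]
}

#' Read a pathway database from attribute-value flat-files
#'
#' Parses the four flat-files of a BioCyc-style pathway database. The dialect
#' is one `ATTRIBUTE - VALUE` pair per line; `//` ends a record; a leading
#' `/` continues the previous value; `#` starts a comment line. Unknown
#' attributes are ignored. The assembled database is checked for referential
#' integrity; dangling references or duplicate record ids are errors.
#'
#' Recognized attributes: compounds `UNIQUE-ID`, `COMMON-NAME`, `SYNONYMS`;
#' reactions `UNIQUE-ID`, `EC-NUMBER`, `LEFT`, `RIGHT`, `REVERSIBLE` (T/F),
#' `IN-PATHWAY`; enzymes `UNIQUE-ID`, `EC-NUMBER` (defaults to the id),
#' `COMMON-NAME`, `GENE`, `PROTEIN`; pathways `UNIQUE-ID`, `COMMON-NAME`.
#'
#' @param compound_file,reaction_file,enzyme_file,pathway_file paths (or
#'   character vectors of lines when `as_lines = TRUE`).
#' @param as_lines interpret the four arguments as already-read lines.
#' @return A [pathway_db()].
#' @export
parse_pathway_flatfiles <- function(compound_file, reaction_file,
                                    enzyme_file, pathway_file,
                                    as_lines = FALSE) {
  get_lines <- function(x) if (as_lines) x else readr::read_lines(x)
  crec <- parse_attr_value(get_lines(compound_file), "compounds")
  rrec <- parse_attr_value(get_lines(reaction_file), "reactions")
  erec <- parse_attr_value(get_lines(enzyme_file), "enzymes")
  prec <- parse_attr_value(get_lines(pathway_file), "pathways")

  need_id <- function(recs, what) {
    ids <- vapply(recs, rec_one, character(1), attr = "UNIQUE-ID")
    if (anyNA(ids) || any(!nzchar(ids))) stop(what, ": record without UNIQUE-ID")
    if (anyDuplicated(ids)) {
      stop(what, ": duplicate record id(s): ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    }
    ids
  }
  cid <- need_id(crec, "compounds")
  rid <- need_id(rrec, "reactions")
  eid <- need_id(erec, "enzymes")
  pid <- need_id(prec, "pathways")

  compounds <- tibble::tibble(
    compound_id = cid,
    name = vapply(crec, function(r) rec_one(r, "COMMON-NAME", rec_one(r, "UNIQUE-ID")), character(1)),
    synonyms = lapply(crec, rec_field, attr = "SYNONYMS")
  )
  reactions <- tibble::tibble(
    reaction_id = rid,
    ec_numbers = lapply(rrec, rec_field, attr = "EC-NUMBER"),
    substrate_ids = lapply(rrec, function(r) sort(unique(rec_field(r, "LEFT")))),
    product_ids = lapply(rrec, function(r) sort(unique(rec_field(r, "RIGHT")))),
    reversible = vapply(rrec, function(r) identical(rec_one(r, "REVERSIBLE", "F"), "T"), logical(1)),
    pathway_ids = lapply(rrec, function(r) sort(unique(rec_field(r, "IN-PATHWAY"))))
  )
  enzymes <- tibble::tibble(
    enzyme_id = eid,
    ec = vapply(erec, function(r) rec_one(r, "EC-NUMBER", rec_one(r, "UNIQUE-ID")), character(1)),
    display_name = vapply(erec, function(r) rec_one(r, "COMMON-NAME", rec_one(r, "UNIQUE-ID")), character(1)),
    gene_ids = lapply(erec, function(r) sort(unique(rec_field(r, "GENE")))),
    protein_ids = lapply(erec, function(r) sort(unique(rec_field(r, "PROTEIN"))))
  )
  pathways <- tibble::tibble(
    pathway_id = pid,
    name = vapply(prec, function(r) rec_one(r, "COMMON-NAME", rec_one(r, "UNIQUE-ID")), character(1))
  )
  db <- pathway_db(compounds, reactions, enzymes, pathways)
  assert_valid_db(db)
  db
}

#' Write a pathway database as attribute-value flat-files
#'
#' Inverse of [parse_pathway_flatfiles()]. Records are written in sorted id
#' order so output is byte-stable for a given database.
#'
#' @param db a [pathway_db()].
#' @param dir output directory; created if missing. Files are named
#'   `compounds.dat`, `reactions.dat`, `enzymes.dat`, `pathways.dat`.
#' @return `dir`, invisibly.
#' @export
write_pathway_flatfiles <- function(db, dir) {
  stopifnot(inherits(db, "pathway_db"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  emit <- function(rows) unlist(rows, use.names = FALSE)
  pair <- function(attr, values) if (length(values)) paste(attr, "-", values) else character()

  co <- db$compounds[order(db$compounds$compound_id), ]
  lines <- emit(lapply(seq_len(nrow(co)), function(i) c(
    pair("UNIQUE-ID", co$compound_id[i]),
    pair("COMMON-NAME", co$name[i]),
    pair("SYNONYMS", co$synonyms[[i]]),
    "//")))
  readr::write_lines(lines, file.path(dir, "compounds.dat"))

  rx <- db$reactions[order(db$reactions$reaction_id), ]
  lines <- emit(lapply(seq_len(nrow(rx)), function(i) c(
    pair("UNIQUE-ID", rx$reaction_id[i]),
    pair("EC-NUMBER", rx$ec_numbers[[i]]),
    pair("LEFT", rx$substrate_ids[[i]]),
    pair("RIGHT", rx$product_ids[[i]]),
    pair("REVERSIBLE", if (rx$reversible[i]) "T" else "F"),
    pair("IN-PATHWAY", rx$pathway_ids[[i]]),
    "//")))
  readr::write_lines(lines, file.path(dir, "reactions.dat"))

  en <- db$enzymes[order(db$enzymes$enzyme_id), ]
  lines <- emit(lapply(seq_len(nrow(en)), function(i) c(
    pair("UNIQUE-ID", en$enzyme_id[i]),
    pair("EC-NUMBER", en$ec[i]),
    pair("COMMON-NAME", en$display_name[i]),
    pair("GENE", en$gene_ids[[i]]),
    pair("PROTEIN", en$protein_ids[[i]]),
    "//")))
  readr::write_lines(lines, file.path(dir, "enzymes.dat"))

  pw <- db$pathways[order(db$pathways$pathway_id), ]
  lines <- emit(lapply(seq_len(nrow(pw)), function(i) c(
    pair("UNIQUE-ID", pw$pathway_id[i]),
    pair("COMMON-NAME", pw$name[i]),
    "//")))
  readr::write_lines(lines, file.path(dir, "pathways.dat"))
  invisible(dir)
}
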