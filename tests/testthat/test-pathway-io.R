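test_that("flat-file parser handles records, comments, continuations", {
  compounds <- c(
    "# a comment line",
    "UNIQUE-ID - C1",
    "COMMON-NAME - alpha",
    "/ with a continued name",
    "SYNONYMS - a1",
    "SYNONYMS - a2",
    "//",
    "UNIQUE-ID - C2",
    "COMMON-NAME - beta",
    "//")
  db <- parse_pathway_flatfiles(
    compounds,
    c("UNIQUE-ID - R1", "EC-NUMBER - 1.1.1.1", "LEFT - C1", "RIGHT - C2",
      "REVERSIBLE - F", "//"),
    c("UNIQUE-ID - 1.1.1.1", "COMMON-NAME - enz", "GENE - AA1G00010", "//"),
    character(), as_lines = TRUE)
  expect_equal(nrow(db$compounds), 2L)
  expect_equal(db$compounds$name[db$compounds$compound_id == "C1"],
               "alpha with a continued name")
  expect_equal(db$compounds$synonyms[[which(db$compounds$compound_id == "C1")]],
               c("a1", "a2"))
  expect_equal(nrow(db$reactions), 1L)
})

test_that("parser reports malformed lines, duplicates and dangling references", {
  expect_error(
    parse_pathway_flatfiles(c("UNIQUE-ID - C1", "BROKEN LINE", "//"),
                            character(), character(), character(), as_lines = TRUE),
    "line 2")
  expect_error(
    parse_pathway_flatfiles(c("UNIQUE-ID - C1", "//", "UNIQUE-ID - C1", "//"),
                            character(), character(), character(), as_lines = TRUE),
    "duplicate")
  expect_error(
    parse_pathway_flatfiles(
      c("UNIQUE-ID - C1", "//"),
      c("UNIQUE-ID - R1", "LEFT - C1", "RIGHT - MISSING", "//"),
      character(), character(), as_lines = TRUE),
    "MISSING")
})

test_that("flat-file write/parse round-trips and is order-insensitive", {
  for (seed in 1:5) {
    db <- make_small_db(seed)
    dir <- withr::local_tempdir()
    write_pathway_flatfiles(db, dir)
    db2 <- parse_pathway_flatfiles(
      file.path(dir, "compounds.dat"), file.path(dir, "reactions.dat"),
      file.path(dir, "enzymes.dat"), file.path(dir, "pathways.dat"))
    for (part in c("compounds", "reactions", "enzymes", "pathways")) {
      a <- dplyr::arrange(db[[part]], dplyr::across(1))
      b <- dplyr::arrange(db2[[part]], dplyr::across(1))
      expect_equal(as.data.frame(a), as.data.frame(b))
    }
  }
  # permuting records leaves the parsed db unchanged
  dir <- withr::local_tempdir()
  write_pathway_flatfiles(make_small_db(1), dir)
  lines <- readr::read_lines(file.path(dir, "compounds.dat"))
  recs <- split(lines, cumsum(dplyr::lag(lines == "//", default = FALSE)))
  permuted <- unlist(rev(recs), use.names = FALSE)
  db_a <- parse_pathway_flatfiles(
    file.path(dir, "compounds.dat"), file.path(dir, "reactions.dat"),
    file.path(dir, "enzymes.dat"), file.path(dir, "pathways.dat"))
  db_b <- parse_pathway_flatfiles(
    permuted,
    readr::read_lines(file.path(dir, "reactions.dat")),
    readr::read_lines(file.path(dir, "enzymes.dat")),
    readr::read_lines(file.path(dir, "pathways.dat")), as_lines = TRUE)
  expect_equal(dplyr::arrange(db_a$compounds, compound_id),
               dplyr::arrange(db_b$compounds, compound_id))
})

test_that("validate_db reports problems without throwing", {
  db <- make_small_db(1)
  expect_equal(nrow(validate_db(db)), 0L)
  bad <- db
  bad$reactions$substrate_ids[[1]] <- c("C01", "NOPE")
  rep <- validate_db(bad)
  expect_true(any(rep$type == "dangling_compound"))
  dup <- db
  dup$enzymes <- dplyr::bind_rows(
    db$enzymes,
    tibble::tibble(enzyme_id = "E-DUP", ec = "1.1.1.1", display_name = "dup",
                   gene_ids = list(character()), protein_ids = list(character())))
  rep <- validate_db(dup)
  expect_true(any(rep$type == "duplicate_ec" & rep$severity == "warning"))
})

test_that("hormone annotation parser enforces the closed vocabulary", {
  ann <- parse_hormone_annotations(
    c("hormone\tpathway_id\trole", "auxin\tPWY-IAA1\tbiosynthesis"),
    as_lines = TRUE)
  expect_equal(nrow(ann), 1L)
  expect_error(
    parse_hormone_annotations(
      c("hormone\tpathway_id\trole", "strigolactone\tPWY-X\tbiosynthesis"),
      as_lines = TRUE),
    "strigolactone")
  fx_ann <- load_crosstalk_fixture()$annotations
  expect_setequal(unique(fx_ann$hormone), hormone_vocabulary())
})

test_that("regulation, PPI and evidence parsers deduplicate and normalize", {
  reg <- parse_regulation_table(c("A\tg1", "A\tg1", "B\tg2"), as_lines = TRUE)
  expect_equal(nrow(reg), 2L)
  ppi <- parse_ppi_table(c("x\ty", "y\tx", "z\tz"), as_lines = TRUE)
  expect_equal(nrow(ppi), 1L)
  expect_equal(ppi$gene_a, "x")
  expect_warning(parse_regulation_table(character(), as_lines = TRUE), "empty")
  ev <- parse_expression_lists(c("g1", "g2", "g1"), "p1", context = "x", as_lines = TRUE)
  expect_equal(ev$expressed_gene_ids, c("g1", "g2"))
  fx_reg <- load_crosstalk_fixture()$regulation
  expect_true(any(fx_reg$tf_gene_id == "AT5G60890" & fx_reg$target_gene_id == "AT2G20610"))
  expect_true(any(fx_reg$tf_gene_id == "AT5G61420" & fx_reg$target_gene_id == "AT2G20610"))
})

test_that("network writers are byte-stable and GraphML round-trips", {
  net <- rand_network(6, 0.5, seed = 42)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_network(net, f1, "sif"); write_network(net, f2, "sif")
  expect_identical(readr::read_file(f1), readr::read_file(f2))
  expect_equal(length(readr::read_lines(f1)), nrow(net$edges))

  one_edge <- crosstalk_network(
    tibble::tibble(id = c("a", "b"), kind = "enzyme"),
    tibble::tibble(from = "a", to = "b", relation = "shares_compound",
                   provenance = list("c1")))
  f3 <- withr::local_tempfile()
  write_network(one_edge, f3, "sif")
  expect_equal(readr::read_lines(f3), "a\tshares_compound\tb")

  g1 <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, g1, "graphml")
  back <- read_network_graphml(g1)
  expect_equal(back$nodes, net$nodes)
  expect_equal(back$edges, net$edges)
  expect_error(write_network(net, withr::local_tempfile(), "xgmml"))
})

test_that("the packaged fixture parses and contains the route enzymes", {
  fx <- load_crosstalk_fixture()
  expect_equal(nrow(validate_db(fx$db)), 0L)
  expect_equal(length(fx$route_enzymes), 13L)
  expect_true(all(fx$route_enzymes %in% fx$db$enzymes$ec))
  expect_true("1.14.17.4" %in% fx$db$enzymes$ec)
})
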