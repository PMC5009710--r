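reg_tbl <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  tibble::tibble(tf_gene_id = m[, 1], target_gene_id = m[, 2])
}

test_that("co-target edges require a shared target and carry it as provenance", {
  net <- build_cotarget_network(reg_tbl("A", "g", "B", "g", "C", "h"))
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$provenance[[1]], "g")
  # disjoint target sets: no edge
  net2 <- build_cotarget_network(reg_tbl("A", "g1", "B", "g2"))
  expect_equal(nrow(net2$edges), 0L)
  # target filter restricts provenance
  net3 <- build_cotarget_network(reg_tbl("A", "g", "B", "g", "A", "h", "B", "h"),
                                 target_filter = "g")
  expect_equal(net3$edges$provenance[[1]], "g")
  # fixture: MYB34 and MYB28 share the SUR1-encoding gene
  fx <- load_crosstalk_fixture()
  tf <- build_cotarget_network(fx$regulation)
  key <- paste(tf$edges$from, tf$edges$to)
  i <- which(key == "AT5G60890 AT5G61420")
  expect_length(i, 1L)
  expect_true("AT2G20610" %in% tf$edges$provenance[[i]])
  # provenance targets really are shared, per the regulation table
  for (k in seq_len(nrow(tf$edges))) {
    a <- tf$edges$from[k]; b <- tf$edges$to[k]
    for (g in tf$edges$provenance[[k]]) {
      expect_true(any(fx$regulation$tf_gene_id == a & fx$regulation$target_gene_id == g))
      expect_true(any(fx$regulation$tf_gene_id == b & fx$regulation$target_gene_id == g))
    }
  }
})

test_that("cycle enumeration is exact against permutation brute force", {
  tri <- rand_network(3, 1, seed = 1)
  expect_equal(length(enumerate_cycles(tri)), 1L)
  expect_equal(length(enumerate_cycles(tri)[[1]]), 3L)
  # two triangles sharing one node
  net <- crosstalk_network(
    tibble::tibble(id = c("a", "b", "c", "d", "e"), kind = "tf"),
    tibble::tibble(from = c("a", "b", "a", "c", "d", "c"),
                   to = c("b", "c", "c", "d", "e", "e"),
                   relation = "co_targets", provenance = as.list(rep("x", 6))))
  expect_equal(length(enumerate_cycles(net)), 2L)
  for (seed in 1:12) {
    rnet <- rand_network(sample(4:8, 1), stats::runif(1, 0.3, 0.7), seed)
    got <- enumerate_cycles(rnet, max_len = 8)
    want <- oracle_cycles(rnet)
    expect_equal(got, want)
  }
  expect_error(enumerate_cycles(tri, max_len = 2), "max_len")
})

test_that("units group edge-sharing cycles; every unit holds at least one cycle", {
  # one triangle whose edges share an enzyme-gene target
  reg <- reg_tbl("A", "g", "B", "g", "B", "h", "C", "h", "C", "i", "A", "i")
  net <- build_cotarget_network(reg)
  units <- assemble_units(enumerate_cycles(net), net, enzyme_gene_set = c("g", "zzz"))
  expect_length(units, 1L)
  expect_setequal(units[[1]]$members, c("A", "B", "C"))
  expect_equal(units[[1]]$regulated_enzyme_genes, "g")
  # two edge-disjoint triangles stay separate units
  net2 <- crosstalk_network(
    tibble::tibble(id = c("a", "b", "c", "d", "e"), kind = "tf"),
    tibble::tibble(from = c("a", "b", "a", "c", "d", "c"),
                   to = c("b", "c", "c", "d", "e", "e"),
                   relation = "co_targets", provenance = as.list(rep("x", 6))))
  units2 <- assemble_units(enumerate_cycles(net2), net2)
  expect_length(units2, 2L)
  # units partition the cycle set
  cyc <- enumerate_cycles(net2)
  expect_equal(sum(vapply(units2, function(u) length(u$cycles), integer(1))),
               length(cyc))
  expect_true(all(vapply(units2, function(u) length(u$cycles) >= 1, logical(1))))
})

test_that("the fixture's unit C contains HY5 and TT2 and its PPI chain", {
  fx <- load_crosstalk_fixture()
  tf <- build_cotarget_network(fx$regulation)
  cyc <- suppressMessages(enumerate_cycles(tf))
  enzyme_genes <- sort(unique(unlist(hormonet:::enzymes_by_ec(fx$db)$gene_ids)))
  units <- assemble_units(cyc, tf, enzyme_genes)
  with_hy5 <- Filter(function(u) "AT5G11260" %in% u$members, units)
  expect_length(with_hy5, 1L)
  unit_c <- with_hy5[[1]]
  expect_true(all(c("AT5G11260", "AT5G35550") %in% unit_c$members))
  expect_setequal(unit_c$regulated_enzyme_genes,
                  c("AT4G22880", "AT5G13930", "AT5G17050"))
  # unit A: TFs co-targeting the NCED9-encoding gene
  with_pil5_fus3 <- Filter(function(u) all(c("AT2G20180", "AT3G26790") %in% u$members), units)
  expect_length(with_pil5_fus3, 1L)
  expect_true("AT1G78390" %in% with_pil5_fus3[[1]]$regulated_enzyme_genes)
  # PPI route through unit C in chain order
  route <- find_ppi_route(unit_c, fx$ppi)
  expect_equal(route, c("AT3G17609", "AT5G11260", "AT1G56650",
                        "AT5G41315", "AT1G63650", "AT5G35550"))
  # no PPI edges among members: empty route
  other <- Filter(function(u) "AT1G32640" %in% u$members, units)[[1]]
  expect_equal(find_ppi_route(other, fx$ppi), character())
})

test_that("PPI routes match brute-force longest paths on random inputs", {
  for (seed in 1:8) {
    net <- rand_network(7, 0.4, seed, prefix = "p")
    unit <- structure(list(members = net$nodes$id, cycles = list(),
                           regulated_enzyme_genes = character()),
                      class = "control_unit")
    ppi <- tibble::tibble(gene_a = net$edges$from, gene_b = net$edges$to)
    route <- find_ppi_route(unit, ppi)
    if (nrow(ppi) == 0) {
      expect_equal(route, character())
    } else {
      expect_equal(length(route), oracle_longest_path_len(net))
    }
  }
})

test_that("planted co-target cycles are recovered across seeds", {
  hits <- 0L
  n_seeds <- 25L
  for (seed in seq_len(n_seeds)) {
    k <- 3L + (seed %% 6L)  # cycle lengths 3..8
    par <- synthesis_params(seed = seed, n_tfs = 25L,
                            planted_cycle_lengths = k,
                            background_cotarget_density = 0.05)
    gen <- generate_regulation(par)
    net <- build_cotarget_network(gen$regulation)
    cyc <- suppressMessages(enumerate_cycles(net, max_len = 10))
    units <- assemble_units(cyc, net)
    planted <- gen$truth$cycles[[1]]
    ok <- any(vapply(units, function(u) all(planted %in% u$members), logical(1)))
    hits <- hits + ok
    # the PPI chain over the planted TFs comes back in chain order
    unit <- structure(list(members = planted, cycles = list(),
                           regulated_enzyme_genes = character()),
                      class = "control_unit")
    route <- find_ppi_route(unit, gen$ppi)
    expect_setequal(route, planted)
  }
  expect_gte(hits / n_seeds, 0.95)
})
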