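test_that("construction collapses duplicates and drops self-loops", {
  expect_message(
    net <- fi_network(tibble::tibble(gene_a = c("A", "B", "A"),
                                     gene_b = c("B", "C", "B"))),
    "duplicate")
  expect_setequal(network_genes(net), c("A", "B", "C"))
  expect_equal(nrow(network_edges(net)), 2)

  expect_message(
    net2 <- fi_network(tibble::tibble(gene_a = c("A", "A"), gene_b = c("A", "B"))),
    "self-loop")
  expect_equal(nrow(network_edges(net2)), 1)

  expect_error(fi_network(tibble::tibble(gene_a = character(0),
                                         gene_b = character(0))),
               "empty")
})

test_that("gene symbols are case-normalized and edge order is canonical", {
  net <- fi_network(tibble::tibble(gene_a = c("tp53", "Mdm2"),
                                   gene_b = c("MDM2", "tp53")))
  expect_setequal(network_genes(net), c("TP53", "MDM2"))
  expect_equal(nrow(network_edges(net)), 1)
  expect_equal(network_edges(net)$gene_a, "MDM2")
})

test_that("largest component picks the biggest part and is identity on connected graphs", {
  # components of size 5 (A..E path) and 3 (X,Y,Z triangle)
  net <- fi_network(tibble::tibble(
    gene_a = c("A", "B", "C", "D", "X", "Y", "Z"),
    gene_b = c("B", "C", "D", "E", "Y", "Z", "X")))
  lcc <- largest_connected_component(net)
  expect_setequal(network_genes(lcc), c("A", "B", "C", "D", "E"))

  tri <- fi_network(tibble::tibble(gene_a = c("A", "B", "C"),
                                   gene_b = c("B", "C", "A")))
  expect_setequal(network_genes(largest_connected_component(tri)),
                  network_genes(tri))
})

test_that("components partition the node set and match a flood-fill oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    g <- igraph::sample_gnp(50, 0.03)
    igraph::V(g)$name <- sprintf("N%02d", 1:50)
    el <- igraph::as_edgelist(g)
    net <- suppressMessages(fi_network(tibble::tibble(gene_a = el[, 1], gene_b = el[, 2]),
                                       nodes = igraph::V(g)$name))
    adj <- adjacency_of(net)
    lab <- oracle_flood_components(adj)
    biggest <- which(tabulate(lab) == max(tabulate(lab)))[1]
    expected <- rownames(adj)[lab == biggest]
    got <- network_genes(largest_connected_component(net))
    if (sum(tabulate(lab) == max(tabulate(lab))) == 1) {
      expect_setequal(got, expected)
    }
    expect_true(length(got) == max(tabulate(lab)))
  }
})

test_that("map_genes matches set intersection and is invariant to order/duplicates", {
  net <- fi_network(tibble::tibble(gene_a = c("A", "B"), gene_b = c("B", "C")))
  m <- map_genes(net, c("A", "B", "Z"))
  expect_setequal(m$in_network, c("A", "B"))
  expect_equal(m$coverage, 0.667)
  expect_equal(map_genes(net, c("a", "b", "c"))$coverage, 1.000)
  expect_error(map_genes(net, character(0)), "empty")

  set.seed(42)
  universe <- sprintf("G%03d", 1:200)
  g_el <- cbind(universe[1:100], universe[2:101])
  bignet <- fi_network(tibble::tibble(gene_a = g_el[, 1], gene_b = g_el[, 2]))
  for (i in 1:100) {
    q <- sample(universe, sample(1:30, 1), replace = TRUE)
    m <- map_genes(bignet, q)
    expect_setequal(m$in_network, intersect(unique(toupper(q)), network_genes(bignet)))
    shuffled <- map_genes(bignet, rev(c(q, q)))
    expect_equal(shuffled$coverage, m$coverage)
    expect_gte(m$coverage, 0)
    expect_lte(m$coverage, 1)
  }
})

test_that("export/reload round-trips the graph and its attributes", {
  net <- fi_network(tibble::tibble(gene_a = c("A", "B", "C"),
                                   gene_b = c("B", "C", "D"),
                                   annotation = c("activates", "inhibits", "unknown")))
  pref <- file.path(withr::local_tempdir(), "net")
  paths <- export_network(net, pref,
                          roles = c(A = "seed", B = "linker"),
                          direction_changes = c(A = 1.2, C = -0.8))

  reread <- read_network(paths[["graphml"]], format = "graphml")
  expect_setequal(network_genes(reread), network_genes(net))
  expect_equal(network_edges(reread), network_edges(net))
  roles <- igraph::vertex_attr(reread$graph, "role")
  names(roles) <- network_genes(reread)
  expect_equal(unname(roles[c("A", "B", "C")]), c("seed", "linker", "seed"))
  dirs <- igraph::vertex_attr(reread$graph, "direction")
  names(dirs) <- network_genes(reread)
  expect_equal(unname(dirs[c("A", "C", "D")]), c("up", "down", "none"))

  resif <- read_network(paths[["sif"]], format = "sif")
  expect_equal(network_edges(resif)[, 1:2], network_edges(net)[, 1:2])

  # a second export of the reloaded network is byte-identical
  pref2 <- file.path(withr::local_tempdir(), "net2")
  paths2 <- export_network(reread, pref2,
                           roles = c(A = "seed", B = "linker"),
                           direction_changes = c(A = 1.2, C = -0.8))
  expect_identical(readLines(paths[["sif"]]), readLines(paths2[["sif"]]))
  expect_identical(readLines(paths[["nodes"]]), readLines(paths2[["nodes"]]))
})

test_that("export writes the documented shapes and validates attribute nodes", {
  net <- fi_network(tibble::tibble(gene_a = "A", gene_b = "B"))
  pref <- file.path(withr::local_tempdir(), "two")
  paths <- export_network(net, pref, roles = c(A = "seed", B = "linker"))
  expect_length(readLines(paths[["sif"]]), 1)
  nodes <- readr::read_tsv(paths[["nodes"]], show_col_types = FALSE)
  expect_equal(nrow(nodes), 2)

  # empty role map: every node defaults to seed
  paths2 <- export_network(net, file.path(withr::local_tempdir(), "dflt"))
  nodes2 <- readr::read_tsv(paths2[["nodes"]], show_col_types = FALSE)
  expect_equal(nodes2$role, c("seed", "seed"))

  expect_error(export_network(net, pref, roles = c(Z = "seed")), "not in the network")
})

test_that("edge-list parsing errors name the offending line", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_a\tgene_b", "A\tB", "C"), f)
  expect_error(read_network(f, format = "tsv"), "line 3")
})
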