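small_cfg <- function(seed = 1, ...) {
  synthetic_config(n_nodes = 120, attachment_m = 2,
                   modules = data.frame(size = c(15, 15), prob = c(0.5, 0.5)),
                   n_de_per_module = 8, rng_seed = seed, ...)
}

test_that("a density-1 module becomes a clique and generation is deterministic", {
  cfg <- synthetic_config(n_nodes = 60, attachment_m = 2,
                          modules = data.frame(size = 10, prob = 1.0),
                          n_de_per_module = 5, rng_seed = 11)
  sim <- generate_network(cfg)
  mod <- sim$truth$module_labels$gene
  sub <- igraph::induced_subgraph(fimodules:::as_igraph(sim$network), mod)
  expect_equal(igraph::ecount(sub), choose(10, 2))

  sim2 <- generate_network(cfg)
  expect_identical(network_edges(sim$network), network_edges(sim2$network))
  expect_identical(sim$truth, sim2$truth)

  sim3 <- generate_network(synthetic_config(n_nodes = 60, attachment_m = 2,
                                            modules = data.frame(size = 10, prob = 1.0),
                                            n_de_per_module = 5, rng_seed = 12))
  expect_false(identical(network_edges(sim$network), network_edges(sim3$network)))
  expect_equal(length(network_genes(sim3$network)), 60)
})

test_that("infeasible configurations are rejected", {
  expect_error(synthetic_config(n_nodes = 20,
                                modules = data.frame(size = 25, prob = 0.5)),
               "exceed")
  expect_error(synthetic_config(modules = data.frame(size = 10, prob = 1.5)),
               "density")
  expect_error(synthetic_config(modules = data.frame(size = 10, prob = 0.005)),
               "density")
  expect_error(synthetic_config(n_de_per_module = 30,
                                modules = data.frame(size = 10, prob = 0.5)),
               "n_de_per_module")
})

test_that("planted modules are denser inside than outside", {
  wins <- 0
  n_rep <- 30
  for (s in seq_len(n_rep)) {
    sim <- generate_network(small_cfg(seed = s))
    g <- fimodules:::as_igraph(sim$network)
    adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
    mod <- sim$truth$module_labels$gene[sim$truth$module_labels$module == 1]
    others <- setdiff(network_genes(sim$network), mod)
    intra <- mean(adj[mod, mod][upper.tri(adj[mod, mod])])
    extra <- mean(adj[mod, others])
    if (intra > extra) wins <- wins + 1
  }
  expect_equal(wins, n_rep)
})

test_that("noiseless expression reproduces planted effects exactly", {
  cfg <- synthetic_config(n_nodes = 80, attachment_m = 2,
                          modules = data.frame(size = 12, prob = 0.5),
                          n_de_per_module = 6, sigma_noise = 0,
                          array_effect_sd = 0, rng_seed = 5)
  sim <- generate_network(cfg)
  ex <- generate_expression(sim$network, sim$truth, cfg)
  vals <- log2(as.matrix(ex$expression[, -1]))
  res <- ex$design$line == "resistant"
  emp_fc <- rowMeans(vals[, res]) - rowMeans(vals[, !res])
  names(emp_fc) <- ex$expression$gene
  expect_equal(unname(emp_fc[sim$truth$planted$gene]),
               sim$truth$planted$effect, tolerance = 1e-10)
  flat <- setdiff(ex$expression$gene, sim$truth$planted$gene)
  expect_equal(max(abs(emp_fc[flat])), 0, tolerance = 1e-10)
  expect_true(all(as.matrix(ex$expression[, -1]) > 0))
})

test_that("the design is a balanced dye swap", {
  cfg <- small_cfg()
  sim <- generate_network(cfg)
  ex <- generate_expression(sim$network, sim$truth, cfg)
  d <- ex$design
  expect_equal(nrow(d), 2 * cfg$n_arrays)
  # each array: one sample per line; dyes balanced within line across arrays
  per_array <- table(d$array, d$line)
  expect_true(all(per_array == 1))
  expect_true(all(table(d$line, d$dye) == cfg$n_arrays / 2))
})

test_that("pathway ground truth mirrors modules with size-matched decoys", {
  cfg <- small_cfg(seed = 3)
  sim <- generate_network(cfg)
  pc <- generate_pathways(sim$network, sim$truth, n_decoy = 5, rng_seed = 3)
  labs <- split(sim$truth$module_labels$gene, sim$truth$module_labels$module)
  expect_equal(pc$pathways[["MODULE_1_PATHWAY"]], sort(labs[[1]]))
  expect_equal(pc$pathways[["MODULE_2_PATHWAY"]], sort(labs[[2]]))
  decoy_sizes <- lengths(pc$pathways[grepl("^DECOY", names(pc$pathways))])
  expect_true(all(decoy_sizes %in% lengths(labs)))
  expect_setequal(pc$background, network_genes(sim$network))
})

test_that("the DE stage recovers planted genes on generator defaults", {
  cfg <- synthetic_config(rng_seed = 77)
  sim <- generate_network(cfg)
  ex <- generate_expression(sim$network, sim$truth, cfg)
  de <- select_de_genes(ex$expression, ex$design)
  recovery <- mean(sim$truth$planted$gene %in% de$gene[de$selected])
  expect_gte(recovery, 0.9)
})

test_that("simulate_inputs writes a loadable bundle", {
  dir <- withr::local_tempdir()
  cfg <- small_cfg(seed = 9)
  paths <- simulate_inputs(cfg, dir)
  expect_true(all(file.exists(paths)))
  net <- read_network(paths[["network"]])
  expect_lte(abs(length(network_genes(net)) - cfg$n_nodes), 1)
  gt <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_setequal(gt$planted$gene, {
    sim <- generate_network(cfg); sim$truth$planted$gene
  })
  pw <- read_gmt(paths[["pathways"]])
  expect_true(any(grepl("MODULE", names(pw))))
})
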