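path_net <- function() {
  fi_network(tibble::tibble(gene_a = c("A", "B"), gene_b = c("B", "C")))
}

test_that("hop distances on small graphs are exact", {
  dm <- pairwise_shortest_paths(path_net(), c("A", "C"))
  expect_equal(dm$d["A", "C"], 2)
  expect_equal(diag(dm$d), c(A = 0, C = 0))

  two_comp <- fi_network(tibble::tibble(gene_a = c("A", "X"), gene_b = c("B", "Y")))
  dm2 <- pairwise_shortest_paths(two_comp, c("A", "X"))
  expect_equal(dm2$d["A", "X"], Inf)

  expect_error(pairwise_shortest_paths(path_net(), c("A", "Q")), "Q")
})

test_that("BFS distances equal the Floyd-Warshall oracle on random graphs", {
  for (i in 1:10) {
    net <- random_connected_net(50, 0.08, seed = 100 + i)
    set.seed(200 + i)
    seeds <- sample(network_genes(net), 10)
    dm <- pairwise_shortest_paths(net, seeds)
    D <- oracle_floyd_warshall(adjacency_of(net))
    expect_equal(dm$d, D[dm$seeds, dm$seeds])
    # typed invariants
    expect_true(isSymmetric(dm$d))
    expect_true(all(diag(dm$d) == 0))
  }
})

test_that("mean pairwise distance averages finite unordered pairs", {
  tri <- fi_network(tibble::tibble(gene_a = c("A", "B", "C"),
                                   gene_b = c("B", "C", "A")))
  expect_equal(mean_pairwise_distance(pairwise_shortest_paths(tri, c("A", "B", "C"))), 1)

  dm <- structure(list(seeds = c("A", "B", "C"),
                       d = matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3,
                                  dimnames = list(c("A", "B", "C"), c("A", "B", "C"))),
                       inf_replacement = NULL),
                  class = "distance_matrix")
  expect_equal(mean_pairwise_distance(dm), 2)

  set.seed(9)
  net <- random_connected_net(30, 0.1, seed = 9)
  seeds <- sample(network_genes(net), 8)
  dm2 <- pairwise_shortest_paths(net, seeds)
  expect_equal(mean_pairwise_distance(dm2), sum(dm2$d[upper.tri(dm2$d)]) / choose(8, 2))

  dm_inf <- structure(list(seeds = c("A", "B"),
                           d = matrix(c(0, Inf, Inf, 0), 2,
                                      dimnames = list(c("A", "B"), c("A", "B"))),
                           inf_replacement = 3),
                      class = "distance_matrix")
  expect_error(mean_pairwise_distance(dm_inf), "finite")
})

test_that("average-linkage core keeps the tight cluster and honors coverage", {
  # 9 mutually close seeds plus one far outlier, exercised at coverage 0.9:
  # expected cut derived by building the dendrogram by hand — the 9 seeds
  # all merge at height 1 (all pairwise distances equal), the outlier joins
  # at its average distance 10, so the first cut reaching 90% retains the 9
  seeds <- sprintf("S%d", 1:10)
  d <- matrix(10, 10, 10, dimnames = list(seeds, seeds))
  d[1:9, 1:9] <- 1
  diag(d) <- 0
  dm <- structure(list(seeds = seeds, d = d, inf_replacement = NULL),
                  class = "distance_matrix")
  core <- average_linkage_core(dm, coverage = 0.9)
  expect_setequal(core$retained, seeds[1:9])
  expect_equal(core$coverage, 0.9)

  # all distances equal: a single merge keeps everything
  d2 <- matrix(2, 4, 4, dimnames = list(seeds[1:4], seeds[1:4])); diag(d2) <- 0
  dm2 <- structure(list(seeds = seeds[1:4], d = d2, inf_replacement = NULL),
                   class = "distance_matrix")
  expect_setequal(average_linkage_core(dm2, 0.9)$retained, seeds[1:4])
  expect_equal(average_linkage_core(dm2, 0.9)$coverage, 1)

  # coverage 1 retains all seeds on any instance
  set.seed(4)
  net <- random_connected_net(40, 0.1, seed = 4)
  sd <- sample(network_genes(net), 12)
  expect_setequal(average_linkage_core(pairwise_shortest_paths(net, sd), 1)$retained,
                  toupper(sd))

  expect_error(average_linkage_core(dm2, 0), "coverage")
  expect_error(average_linkage_core(dm2, 1.2), "coverage")
})

test_that("unreachable seeds merge last via the diameter-based height", {
  net <- fi_network(tibble::tibble(gene_a = c("A", "B", "X"),
                                   gene_b = c("B", "C", "Y")))
  dm <- pairwise_shortest_paths(net, c("A", "B", "C", "X"))
  expect_equal(dm$inf_replacement, 3)  # largest-component diameter 2, plus 1
  core <- average_linkage_core(dm, coverage = 0.75)
  expect_setequal(core$retained, c("A", "B", "C"))
})

test_that("permutation p-value uses the add-one estimator", {
  expect_equal(fimodules:::permutation_pvalue(1.0, rep(2, 999)), 1 / 1000)
  expect_equal(fimodules:::permutation_pvalue(2.0, c(1.5, 1.8, 3.0)), 3 / 4)
  expect_equal(fimodules:::permutation_pvalue(5, rep(1, 9)), 1)
})

test_that("permutation test is reproducible, order-invariant, and excludes stray seeds", {
  net <- random_connected_net(60, 0.07, seed = 31)
  seeds <- sample(network_genes(net), 8)
  p1 <- permutation_test(net, seeds, B = 50, rng_seed = 5)
  p2 <- permutation_test(net, seeds, B = 50, rng_seed = 5)
  expect_identical(p1$null_values, p2$null_values)
  expect_equal(p1$p_value, p2$p_value)
  p3 <- permutation_test(net, rev(seeds), B = 50, rng_seed = 5)
  expect_equal(p3$observed, p1$observed)
  expect_gte(p1$p_value, 1 / 51)
  expect_lte(p1$p_value, 1)

  # a seed in a detached component is dropped from the statistic
  el <- network_edges(net)
  net2 <- fi_network(dplyr::bind_rows(el, tibble::tibble(gene_a = "ZZ1", gene_b = "ZZ2",
                                                         annotation = "unknown")))
  expect_message(p4 <- permutation_test(net2, c(seeds, "ZZ1"), B = 20, rng_seed = 1),
                 "excluded 1")
  expect_equal(p4$n_excluded, 1)
  expect_equal(p4$n_seeds, length(seeds))

  expect_error(permutation_test(net, seeds, B = 0), "B")
})

test_that("planted dense modules give small proximity p-values", {
  hits <- 0
  n_seeds_tested <- 8
  for (s in 1:n_seeds_tested) {
    cfg <- synthetic_config(n_nodes = 200, modules = data.frame(size = 20, prob = 0.4),
                            n_de_per_module = 12, rng_seed = 400 + s)
    sim <- generate_network(cfg)
    pt <- permutation_test(sim$network, sim$truth$planted$gene, B = 99,
                           rng_seed = 500 + s)
    if (pt$p_value <= 0.05) hits <- hits + 1
  }
  expect_gte(hits, n_seeds_tested - 1)
})
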