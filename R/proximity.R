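# Network proximity of the seed genes: pairwise shortest-path hop counts,
# average-linkage selection of the interconnected core, and the permutation
# test for the average shortest path.

#' Pairwise shortest-path distances among seed genes
#'
#' Unweighted (hop-count) breadth-first distances between every pair of seed
#' genes; pairs in different components get `Inf`. When infinities are
#' present, the matrix also records the replacement height used downstream
#' by [average_linkage_core()] (diameter of the largest component + 1), so
#' unreachable seeds merge last.
#'
#' @param net an `fi_network`.
#' @param seeds character vector of at least two seed genes, all present in
#'   the network.
#' @return An object of class `distance_matrix`: fields `seeds` and `d`
#'   (symmetric hop-count matrix).
#' @export
pairwise_shortest_paths <- function(net, seeds) {
  g <- as_igraph(net)
  seeds <- unique(normalize_genes(seeds))
  if (length(seeds) < 2) abort("need at least 2 seed genes")
  miss <- setdiff(seeds, igraph::V(g)$name)
  if (length(miss) > 0) {
    abort(sprintf("seed gene(s) not in network: %s", paste(sort_c(miss), collapse = ", ")))
  }
  d <- igraph::distances(g, v = seeds, to = seeds, algorithm = "unweighted")
  inf_replacement <- NULL
  if (any(is.infinite(d))) {
    lcc <- largest_connected_component(net)
    inf_replacement <- igraph::diameter(lcc$graph, unconnected = FALSE) + 1
  }
  structure(list(seeds = seeds, d = d, inf_replacement = inf_replacement),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("<distance_matrix> %d seeds, %d unreachable pair(s)\n",
              length(x$seeds), sum(is.infinite(x$d[upper.tri(x$d)]))))
  invisible(x)
}

#' Mean pairwise shortest-path distance
#'
#' Mean hop count over all finite unordered seed pairs — the statistic whose
#' permutation null quantifies how tightly a gene set clusters in the
#' network.
#'
#' @param dm a `distance_matrix` from [pairwise_shortest_paths()].
#' @return A single number.
#' @export
mean_pairwise_distance <- function(dm) {
  stopifnot(inherits(dm, "distance_matrix"))
  v <- dm$d[upper.tri(dm$d)]
  v <- v[is.finite(v)]
  if (length(v) == 0) abort("no finite seed pair: seeds are mutually unreachable")
  mean(v)
}

#' Average-linkage core selection
#'
#' Hierarchically clusters the seeds on their hop-count dissimilarities
#' (average linkage) and cuts the dendrogram at the smallest height at which
#' the largest cluster holds at least `coverage` of the seeds; that cluster
#' is the "interconnected core" carried into linker inference. Infinite
#' distances are replaced by the recorded replacement height (largest
#' component diameter + 1) so unreachable seeds merge last.
#'
#' @param dm a `distance_matrix`.
#' @param coverage minimum fraction of seeds the selected cluster must
#'   contain (default 0.90, "more than 90% of altered genes").
#' @return An object of class `core_selection`: fields `retained`,
#'   `coverage` (fraction actually retained) and `cut_height`.
#' @export
average_linkage_core <- function(dm, coverage = 0.90) {
  stopifnot(inherits(dm, "distance_matrix"))
  check_fraction(coverage, "coverage")
  d <- dm$d
  if (any(is.infinite(d))) {
    repl <- dm$inf_replacement %||% (max(d[is.finite(d)]) + 1)
    d[is.infinite(d)] <- repl
  }
  n <- length(dm$seeds)
  hc <- hclust(as.dist(d), method = "average")
  heights <- sort(unique(c(0, hc$height)))
  for (h in heights) {
    cl <- cutree(hc, h = h)
    sizes <- table(cl)
    if (max(sizes) / n >= coverage) {
      big <- as.integer(names(sizes)[sizes == max(sizes)])
      if (length(big) > 1) {   # tie: cluster holding the lexicographically smallest seed
        smallest <- vapply(big, function(k) min(sort_c(dm$seeds[cl == k])), character(1))
        big <- big[order(smallest)][1]
      }
      retained <- sort_c(dm$seeds[cl == big])
      return(structure(list(retained = retained,
                            coverage = length(retained) / n,
                            cut_height = h),
                       class = "core_selection"))
    }
  }
  structure(list(retained = sort_c(dm$seeds), coverage = 1, cut_height = max(heights)),
            class = "core_selection")
}

#' @export
print.core_selection <- function(x, ...) {
  cat(sprintf("<core_selection> %d seed(s) retained (coverage %.3f, cut height %.3f)\n",
              length(x$retained), x$coverage, x$cut_height))
  invisible(x)
}

# add-one permutation p-value: never 0, floor 1/(B+1)
permutation_pvalue <- function(observed, null_values) {
  (1 + sum(null_values <= observed)) / (length(null_values) + 1)
}

#' Permutation test for the average shortest path
#'
#' Tests whether the seed genes lie closer together in the network than
#' random gene sets of the same size. The null draws `B` uniform
#' without-replacement samples from the largest connected component and
#' recomputes the mean pairwise hop distance for each; the p-value is the
#' add-one estimator `(1 + #{null <= observed}) / (B + 1)`. Seeds outside
#' the largest component are excluded from the statistic (a message reports
#' how many).
#'
#' @param net an `fi_network`.
#' @param seeds seed genes (at least two inside the largest component).
#' @param B number of permutations (default 1000).
#' @param rng_seed integer seed; runs with the same seed are identical.
#' @return An object of class `permutation_test`: `observed`,
#'   `null_values`, `p_value`, `B`, `n_seeds`, `n_excluded`;
#'   see [tidy.permutation_test()] and [glance.permutation_test()].
#' @export
permutation_test <- function(net, seeds, B = 1000, rng_seed = 1L) {
  if (!is_count(B)) abort("`B` must be a positive integer")
  seeds <- unique(normalize_genes(seeds))
  lcc <- largest_connected_component(net)
  comp_genes <- network_genes(lcc)
  inside <- seeds[seeds %in% comp_genes]
  n_excluded <- length(seeds) - length(inside)
  if (n_excluded > 0) {
    inform(sprintf("excluded %d seed(s) outside the largest connected component", n_excluded))
  }
  if (length(inside) < 2) abort("fewer than 2 seeds in the largest connected component")
  if (length(inside) > length(comp_genes)) abort("more seeds than component genes")

  d_all <- igraph::distances(lcc$graph, algorithm = "unweighted")
  ut <- upper.tri(matrix(0, length(inside), length(inside)))
  idx <- match(inside, comp_genes)
  observed <- mean(d_all[idx, idx][ut])

  set.seed(rng_seed)
  k <- length(inside)
  nv <- length(comp_genes)
  null_values <- vapply(seq_len(B), function(b) {
    s <- sample.int(nv, k)
    mean(d_all[s, s][ut])
  }, numeric(1))

  structure(list(observed = observed,
                 null_values = null_values,
                 p_value = permutation_pvalue(observed, null_values),
                 B = as.integer(B),
                 n_seeds = k,
                 n_excluded = n_excluded,
                 rng_seed = as.integer(rng_seed)),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("<permutation_test> observed mean distance %.3f over %d seeds; p = %.4g (B = %d)\n",
              x$observed, x$n_seeds, x$p_value, x$B))
  invisible(x)
}
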