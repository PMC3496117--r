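# Independent oracles used across the test files. Each reimplements the
# quantity under test by a different route than the package (brute force,
# closed form, or a textbook dense iteration).

# all-pairs shortest paths by Floyd-Warshall (package route is BFS)
oracle_floyd_warshall <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n, dimnames = dimnames(adj))
  D[adj > 0] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], `+`))
  D
}

# connected-component labelling by explicit flood fill
oracle_flood_components <- function(adj) {
  n <- nrow(adj)
  label <- rep(0L, n)
  current <- 0L
  for (s in seq_len(n)) {
    if (label[s] == 0L) {
      current <- current + 1L
      queue <- s
      while (length(queue) > 0) {
        v <- queue[[1]]; queue <- queue[-1]
        if (label[v] == 0L) {
          label[v] <- current
          queue <- c(queue, which(adj[v, ] > 0 & label == 0L))
        }
      }
    }
  }
  label
}

# Benjamini-Hochberg q-values straight from the step-up definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  qs <- p[o] * m / seq_len(m)
  qs <- pmin(rev(cummin(rev(qs))), 1)
  q <- numeric(m)
  q[o] <- qs
  q
}

# textbook dense MCL iteration (expansion 2), kept deliberately simple.
# Returns the limit matrix and a cluster labelling: attractors are nodes
# with positive return probability, attractor systems are flood-fill
# components of the attractor-attractor nonzero pattern, every node joins
# the systems it flows into, and a node attracted to several systems joins
# the larger provisional cluster (ties to the one holding the
# alphabetically first node).
oracle_mcl <- function(adj, inflation = 1.6, prune = 1e-5, tol = 1e-6,
                       max_iter = 200) {
  n <- nrow(adj)
  nodes <- rownames(adj)
  A <- (adj > 0) * 1
  diag(A) <- 1
  M <- A
  for (j in seq_len(n)) M[, j] <- A[, j] / sum(A[, j])
  for (it in seq_len(max_iter)) {
    E <- M %*% M
    for (j in seq_len(n)) {
      col <- E[, j]^inflation
      col[col < prune] <- 0
      if (sum(col) == 0) col[j] <- 1
      E[, j] <- col / sum(col)
    }
    delta <- max(abs(E - M))
    M <- E
    if (delta < tol) break
  }
  att <- which(diag(M) > prune)
  patt <- (M[att, att, drop = FALSE] > 0) | t(M[att, att, drop = FALSE] > 0)
  sys <- oracle_flood_components(patt * 1)
  provisional <- lapply(seq_len(max(sys)), function(s) {
    a <- att[sys == s]
    sort(unique(c(a, which(colSums(M[a, , drop = FALSE] > 0) > 0))))
  })
  labels <- integer(n)
  for (j in seq_len(n)) {
    owners <- which(vapply(provisional, function(m) j %in% m, logical(1)))
    if (length(owners) > 1) {
      sz <- lengths(provisional[owners])
      owners <- owners[sz == max(sz)]
      if (length(owners) > 1) {
        owners <- owners[order(vapply(owners, function(s) min(nodes[provisional[[s]]]), character(1)))]
      }
    }
    labels[j] <- if (length(owners) == 0) NA_integer_ else owners[1]
  }
  if (anyNA(labels)) labels[is.na(labels)] <- max(labels, na.rm = TRUE) + seq_len(sum(is.na(labels)))
  list(M = M, labels = labels)
}

# exhaustive minimum Steiner-node search: smallest number of non-seed nodes
# whose addition makes the seeds mutually connected in the induced subgraph
oracle_min_steiner_nodes <- function(g, seeds) {
  others <- setdiff(igraph::V(g)$name, seeds)
  for (k in 0:length(others)) {
    combs <- utils::combn(others, k)
    if (k == 0) combs <- matrix(character(0), nrow = 0, ncol = 1)
    for (ci in seq_len(ncol(combs))) {
      nodes <- c(seeds, combs[, ci])
      sub <- igraph::induced_subgraph(g, nodes)
      if (igraph::is_connected(sub)) return(k)
    }
  }
  Inf
}

# exact upper-tail binomial probability by direct pmf summation
oracle_binom_upper <- function(k, n, p0) {
  if (k <= 0) return(1)
  sum(vapply(k:n, function(i) choose(n, i) * p0^i * (1 - p0)^(n - i), numeric(1)))
}

# labels-agreement helpers
partition_same <- function(a, b) {
  # TRUE iff two integer labelings induce the same partition
  length(unique(a)) == length(unique(b)) &&
    all(tapply(b, a, function(x) length(unique(x))) == 1)
}

# small random connected G(n, p) graph as an fi_network
random_connected_net <- function(n, p, seed) {
  set.seed(seed)
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g)) break
  }
  igraph::V(g)$name <- sprintf("N%02d", seq_len(n))
  el <- igraph::as_edgelist(g)
  fi_network(tibble::tibble(gene_a = el[, 1], gene_b = el[, 2]))
}

adjacency_of <- function(net) {
  igraph::as_adjacency_matrix(fimodules:::as_igraph(net), sparse = FALSE)
}

# the fixed small-graph family used for MCL oracle equivalence
mcl_test_family <- function() {
  make <- function(edges, n) {
    g <- igraph::make_graph(edges, n = n, directed = FALSE)
    igraph::V(g)$name <- LETTERS[seq_len(n)]
    g
  }
  fam <- list()
  for (n in 3:8) {
    fam[[sprintf("path_%d", n)]] <- make(rbind(1:(n - 1), 2:n), n)
    fam[[sprintf("cycle_%d", n)]] <- make(rbind(1:n, c(2:n, 1)), n)
    fam[[sprintf("star_%d", n)]] <- make(rbind(rep(1, n - 1), 2:n), n)
    fam[[sprintf("clique_%d", n)]] <- make(t(utils::combn(n, 2)) |> t(), n)
  }
  # two cliques joined by a single edge
  for (k in c(3, 4)) {
    e <- rbind(t(utils::combn(1:k, 2)), t(utils::combn((k + 1):(2 * k), 2)), c(k, k + 1))
    fam[[sprintf("two_cliques_%d", k)]] <- make(t(e), 2 * k)
  }
  fam
}
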