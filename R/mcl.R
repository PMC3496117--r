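# Markov Cluster Algorithm, written from scratch on a dense column-stochastic
# matrix. Alternates expansion (matrix power, simulating flow) with inflation
# (entrywise power + column renormalisation, strengthening strong flows) until
# the matrix stops changing; clusters are read off the limit's attractor
# systems.

# one full MCL iteration loop; returns the limit matrix plus diagnostics
mcl_iterate <- function(M, inflation, expansion, prune_threshold,
                        convergence_tol, max_iter) {
  colsum_dev <- 0
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    Mx <- M
    for (e in seq_len(expansion - 1)) Mx <- Mx %*% M
    Mx <- Mx^inflation
    Mx[Mx < prune_threshold] <- 0
    cs <- colSums(Mx)
    dead <- which(cs == 0)
    if (length(dead) > 0) {        # a fully pruned column restarts at its own node
      Mx[cbind(dead, dead)] <- 1
      cs[dead] <- 1
    }
    Mx <- sweep(Mx, 2, cs, "/")
    colsum_dev <- max(colsum_dev, max(abs(colSums(Mx) - 1)))
    delta <- max(abs(Mx - M))
    M <- Mx
    if (delta < convergence_tol) { converged <- TRUE; break }
  }
  list(M = M, iterations = iter, converged = converged, colsum_dev = colsum_dev)
}

# read clusters off the limit matrix: attractors are nodes with positive
# return probability; attractor systems are connected components of the
# nonzero pattern restricted to attractors; every node joins the system(s)
# it flows into, overlaps resolved to the larger provisional cluster
# (ties to the one holding the lexicographically smallest gene)
mcl_interpret <- function(M, genes, prune_threshold) {
  n <- length(genes)
  attractors <- which(diag(M) > prune_threshold)
  if (length(attractors) == 0) attractors <- seq_len(n)   # degenerate safeguard
  A <- (M[attractors, attractors, drop = FALSE] > 0) |
       t(M[attractors, attractors, drop = FALSE] > 0)
  sys_of <- integer(length(attractors))
  s <- 0L
  for (i in seq_along(attractors)) {          # flood fill over attractor pattern
    if (sys_of[i] == 0L) {
      s <- s + 1L
      queue <- i
      while (length(queue) > 0) {
        v <- queue[[1]]; queue <- queue[-1]
        if (sys_of[v] == 0L) {
          sys_of[v] <- s
          queue <- c(queue, which(A[v, ] & sys_of == 0L))
        }
      }
    }
  }
  # provisional membership: node j belongs to system k if it flows into any
  # of k's attractors
  members <- lapply(seq_len(s), function(k) {
    att_k <- attractors[sys_of == k]
    which(colSums(M[att_k, , drop = FALSE] > 0) > 0)
  })
  for (k in seq_len(s)) members[[k]] <- sort(unique(c(members[[k]], attractors[sys_of == k])))

  assign <- integer(n)
  for (j in seq_len(n)) {
    owning <- which(vapply(members, function(m) j %in% m, logical(1)))
    if (length(owning) == 0) {
      assign[j] <- NA_integer_
    } else if (length(owning) == 1) {
      assign[j] <- owning
    } else {
      sizes <- lengths(members[owning])
      best <- owning[sizes == max(sizes)]
      if (length(best) > 1) {
        first_gene <- vapply(best, function(k) min(sort_c(genes[members[[k]]])), character(1))
        best <- best[order(first_gene)][1]
      } else {
        best <- best[1]
      }
      assign[j] <- best
    }
  }
  # unreachable nodes (fully pruned away) become singletons
  if (anyNA(assign)) {
    extra <- which(is.na(assign))
    assign[extra] <- s + seq_along(extra)
  }
  assign
}

#' Cluster a network with the Markov Cluster Algorithm
#'
#' Adds self-loops, column-normalises the adjacency matrix to a random-walk
#' transition matrix, and alternates expansion (matrix power) with inflation
#' (entrywise power followed by column renormalisation and pruning of
#' entries below `prune_threshold`) until the maximum entry change falls
#' below `convergence_tol`. The inflation exponent controls granularity;
#' 1.6 is the coarse setting used for resistance-signature subnetworks.
#'
#' @param x a `linker_subnetwork`, `fi_network` or igraph object.
#' @param inflation entrywise exponent, must exceed 1 (default 1.6).
#' @param expansion matrix power per iteration (default 2).
#' @param prune_threshold entries below this are zeroed each iteration
#'   (default 1e-5), with per-column renormalisation after pruning.
#' @param convergence_tol stop when no entry changes by more than this
#'   (default 1e-6).
#' @param max_iter iteration cap; non-convergence raises a warning and the
#'   current interpretation is returned flagged (default 200).
#' @param self_loop_weight weight of the added self-loops (default 1).
#' @return An object of class `mcl_clusters`: `membership` (tibble `gene`,
#'   `cluster`), `summary` (tibble `cluster`, `size`), `params`,
#'   `converged`, `iterations`. Clusters are numbered by decreasing size
#'   (ties by smallest member gene).
#' @examples
#' tri2 <- fi_network(tibble::tibble(
#'   gene_a = c("A", "A", "B", "D", "D", "E", "C"),
#'   gene_b = c("B", "C", "C", "E", "F", "F", "D")))
#' mcl_cluster(tri2)$summary
#' @export
mcl_cluster <- function(x, inflation = 1.6, expansion = 2L,
                        prune_threshold = 1e-5, convergence_tol = 1e-6,
                        max_iter = 200L, self_loop_weight = 1) {
  if (!is.numeric(inflation) || inflation <= 1) abort("`inflation` must exceed 1")
  if (!is_count(expansion) || expansion < 2) abort("`expansion` must be an integer >= 2")
  if (prune_threshold <= 0 || convergence_tol <= 0) abort("thresholds must be positive")
  if (self_loop_weight <= 0) abort("`self_loop_weight` must be positive")
  g <- as_igraph(x)
  if (igraph::vcount(g) == 0) abort("empty network")
  genes <- igraph::V(g)$name
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  A[A > 0] <- 1
  diag(A) <- self_loop_weight
  M <- sweep(A, 2, colSums(A), "/")

  res <- mcl_iterate(M, inflation, expansion, prune_threshold,
                     convergence_tol, max_iter)
  if (!res$converged) {
    warn(sprintf("MCL did not converge within %d iterations; interpreting current matrix", max_iter))
  }
  assign <- mcl_interpret(res$M, genes, prune_threshold)

  # renumber by decreasing size, ties by lexicographically smallest member
  split_genes <- split(genes, assign)
  ord <- order(-lengths(split_genes),
               vapply(split_genes, function(m) min(sort_c(m)), character(1)),
               method = "radix")
  membership <- bind_rows(lapply(seq_along(ord), function(newk) {
    tibble(gene = sort_c(split_genes[[ord[newk]]]), cluster = newk)
  }))

  params <- list(inflation = inflation, expansion = as.integer(expansion),
                 prune_threshold = prune_threshold,
                 convergence_tol = convergence_tol,
                 max_iter = as.integer(max_iter),
                 self_loop_weight = self_loop_weight)
  structure(list(
    membership = membership,
    summary = membership |> dplyr::count(.data$cluster, name = "size"),
    params = params,
    converged = res$converged,
    iterations = res$iterations,
    colsum_dev = res$colsum_dev,
    n_nodes = length(genes)
  ), class = "mcl_clusters")
}

#' Apply the cluster size filters
#'
#' Marks as `retained` every cluster whose size is at least
#' `ceiling(min_fraction * n_nodes)` — by default 2% of the clustered
#' (linker-augmented) subnetwork — and flags clusters larger than
#' `report_min_size` genes for reporting.
#'
#' @param cs an `mcl_clusters` object.
#' @param min_fraction minimum cluster size as a fraction of the clustered
#'   network (default 0.02).
#' @param report_min_size clusters strictly larger than this are flagged
#'   `reported` (default 20).
#' @return The `mcl_clusters` object with `retained` and `reported` columns
#'   added to `summary`, and the thresholds recorded.
#' @export
filter_clusters <- function(cs, min_fraction = 0.02, report_min_size = 20) {
  stopifnot(inherits(cs, "mcl_clusters"))
  check_fraction(min_fraction, "min_fraction")
  threshold <- ceiling(min_fraction * cs$n_nodes)
  cs$summary <- cs$summary |>
    mutate(retained = .data$size >= threshold,
           reported = .data$size > report_min_size)
  cs$min_fraction <- min_fraction
  cs$report_min_size <- report_min_size
  cs$size_threshold <- threshold
  cs
}

#' @export
print.mcl_clusters <- function(x, ...) {
  cat(sprintf("<mcl_clusters> %d node(s) in %d cluster(s) (inflation %g, %d iteration(s)%s)\n",
              x$n_nodes, nrow(x$summary), x$params$inflation, x$iterations,
              if (x$converged) "" else ", NOT converged"))
  if (!is.null(x$summary$retained)) {
    cat(sprintf("  %d cluster(s) retained at size >= %d\n",
                sum(x$summary$retained), x$size_threshold))
  }
  invisible(x)
}

#' Cluster members of a single cluster
#'
#' @param cs an `mcl_clusters` object.
#' @param cluster cluster id.
#' @return Character vector of gene symbols.
#' @export
cluster_members <- function(cs, cluster) {
  stopifnot(inherits(cs, "mcl_clusters"))
  cs$membership$gene[cs$membership$cluster == cluster]
}
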