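# Linker inference: connect the retained seeds into one subnetwork by an
# MST-over-shortest-paths heuristic (a classical 2-approximation to the
# node-weighted Steiner problem). Every tie is broken deterministically so
# identical inputs give identical subnetworks.

# Kruskal MST on the complete seed graph; edges sorted by (weight, a, b)
kruskal_mst <- function(edges) {
  # edges: tibble a, b, w with a < b
  ord <- order(edges$w, edges$a, edges$b, method = "radix")
  nodes <- sort_c(unique(c(edges$a, edges$b)))
  parent <- setNames(seq_along(nodes), nodes)
  find <- function(i) { while (parent[[i]] != i) i <- parent[[i]]; i }
  picked <- integer(0)
  for (e in ord) {
    ra <- find(match(edges$a[[e]], nodes))
    rb <- find(match(edges$b[[e]], nodes))
    if (ra != rb) {
      parent[[ra]] <- rb
      picked <- c(picked, e)
      if (length(picked) == length(nodes) - 1) break
    }
  }
  edges[picked, , drop = FALSE]
}

# lexicographically smallest shortest path from `from` to `to`:
# greedily step to the smallest-named neighbour that stays on a geodesic
lex_shortest_path <- function(g, from, to) {
  d_to <- igraph::distances(g, to = to, algorithm = "unweighted")[, 1]
  if (is.infinite(d_to[[from]])) abort(sprintf("no path between %s and %s", from, to))
  path <- from
  cur <- from
  while (cur != to) {
    nb <- igraph::V(g)$name[igraph::neighbors(g, cur)]
    cand <- nb[d_to[nb] == d_to[[cur]] - 1]
    cur <- sort_c(cand)[1]
    path <- c(path, cur)
  }
  path
}

#' Infer linker genes connecting the seed set
#'
#' Connects all seed genes into a single subnetwork by adding a small set of
#' non-seed "linker" genes: (i) build the complete graph on the seeds
#' weighted by hop distance; (ii) take its minimum spanning tree (Kruskal,
#' ties broken on sorted gene names); (iii) expand every tree edge into one
#' concrete shortest path in the network (the lexicographically smallest
#' geodesic); (iv) linkers are the non-seed genes on those paths. The
#' returned subnetwork is the induced subgraph on seeds plus linkers, i.e.
#' it keeps every network edge among the selected genes, not only the tree
#' edges.
#'
#' @param net an `fi_network`.
#' @param seeds seed genes, mutually reachable in `net` (restrict to the
#'   largest component first if needed).
#' @return An object of class `linker_subnetwork`: fields `seeds`,
#'   `linkers` (disjoint from seeds) and `graph` (the induced igraph).
#' @examples
#' net <- fi_network(tibble::tibble(gene_a = c("A", "B"), gene_b = c("B", "C")))
#' infer_linkers(net, c("A", "C"))$linkers
#' @export
infer_linkers <- function(net, seeds) {
  g <- as_igraph(net)
  seeds <- sort_c(unique(normalize_genes(seeds)))
  miss <- setdiff(seeds, igraph::V(g)$name)
  if (length(miss) > 0) {
    abort(sprintf("seed gene(s) not in network: %s", paste(miss, collapse = ", ")))
  }
  if (length(seeds) == 0) abort("empty seed set")

  if (length(seeds) == 1) {
    sub <- igraph::induced_subgraph(g, seeds)
    return(structure(list(seeds = seeds, linkers = character(0), graph = sub),
                     class = "linker_subnetwork"))
  }

  d <- igraph::distances(g, v = seeds, to = seeds, algorithm = "unweighted")
  if (any(is.infinite(d))) {
    comp <- igraph::components(g)
    grp <- split(seeds, comp$membership[match(seeds, igraph::V(g)$name)])
    abort(paste0("seed genes are not mutually reachable; components: ",
                 paste(vapply(grp, function(x) paste0("{", paste(x, collapse = ","), "}"),
                              character(1)), collapse = " ")))
  }

  pairs <- which(upper.tri(d), arr.ind = TRUE)
  complete <- tibble(a = seeds[pairs[, 1]], b = seeds[pairs[, 2]],
                     w = d[pairs]) |>
    mutate(a2 = pmin(.data$a, .data$b), b2 = pmax(.data$a, .data$b)) |>
    select(a = "a2", b = "b2", w = "w")
  mst <- kruskal_mst(complete)

  path_nodes <- unique(unlist(lapply(seq_len(nrow(mst)), function(i) {
    lex_shortest_path(g, mst$a[[i]], mst$b[[i]])
  })))
  linkers <- sort_c(setdiff(path_nodes, seeds))
  sub <- igraph::induced_subgraph(g, sort_c(c(seeds, linkers)))
  structure(list(seeds = seeds, linkers = linkers, graph = sub),
            class = "linker_subnetwork")
}

#' @export
print.linker_subnetwork <- function(x, ...) {
  cat(sprintf("<linker_subnetwork> %d genes (%d seeds + %d linkers), %d interactions\n",
              igraph::vcount(x$graph), length(x$seeds), length(x$linkers),
              igraph::ecount(x$graph)))
  invisible(x)
}

#' Node roles of a linker subnetwork as a tibble
#'
#' @param x a `linker_subnetwork`.
#' @param ... unused.
#' @return A tibble with columns `gene` and `role` (`seed`/`linker`).
#' @method tidy linker_subnetwork
#' @export
tidy.linker_subnetwork <- function(x, ...) {
  tibble(gene = igraph::V(x$graph)$name) |>
    mutate(role = ifelse(.data$gene %in% x$linkers, "linker", "seed")) |>
    arrange(.data$gene)
}
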