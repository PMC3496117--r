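#' Build a functional-interaction network from an edge table
#'
#' An FI network is a simple undirected graph over gene symbols. It is the
#' background universe for every statistic in the pipeline: permutation nulls
#' are drawn from its largest connected component and enrichment background
#' fractions are computed over its node set. Gene symbols are upper-cased
#' before any matching, self-loops are dropped and duplicate edges collapsed
#' (both reported via a message when present).
#'
#' @param edges data frame whose first two columns are the interacting gene
#'   symbols (`gene_a`, `gene_b`); an optional third column annotates each
#'   edge as `"activates"`, `"inhibits"`, `"indirect"` or `"unknown"`.
#'   Annotations are carried through to exports but ignored by all statistics.
#' @param nodes optional character vector of additional (isolated) gene
#'   symbols to declare as network members.
#' @return An object of class `fi_network`.
#' @examples
#' net <- fi_network(tibble::tibble(gene_a = c("A", "B"), gene_b = c("B", "C")))
#' network_genes(net)
#' @export
fi_network <- function(edges, nodes = NULL) {
  if (!is.data.frame(edges)) abort("`edges` must be a data frame")
  if (nrow(edges) == 0 && length(nodes) == 0) abort("empty network: no edges and no nodes")
  if (nrow(edges) > 0 && ncol(edges) < 2) abort("`edges` needs at least two columns")

  if (nrow(edges) > 0) {
    ga <- normalize_genes(edges[[1]])
    gb <- normalize_genes(edges[[2]])
    if (anyNA(ga) || anyNA(gb) || any(ga == "") || any(gb == "")) {
      abort("missing gene symbol in edge table")
    }
    ann <- if (ncol(edges) >= 3) as.character(edges[[3]]) else rep("unknown", length(ga))
    ann[is.na(ann) | ann == ""] <- "unknown"
    bad <- setdiff(unique(ann), c("activates", "inhibits", "indirect", "unknown"))
    if (length(bad) > 0) {
      abort(sprintf("unknown edge annotation(s): %s", paste(bad, collapse = ", ")))
    }

    loops <- ga == gb
    if (any(loops)) {
      inform(sprintf("dropped %d self-loop(s)", sum(loops)))
      ga <- ga[!loops]; gb <- gb[!loops]; ann <- ann[!loops]
    }
    a <- pmin(ga, gb); b <- pmax(ga, gb)
    dup <- duplicated(paste(a, b, sep = "\r"))
    if (any(dup)) {
      inform(sprintf("collapsed %d duplicate edge(s)", sum(dup)))
      a <- a[!dup]; b <- b[!dup]; ann <- ann[!dup]
    }
  } else {
    a <- b <- ann <- character(0)
  }

  vertices <- sort_c(unique(c(a, b, normalize_genes(nodes %||% character(0)))))
  if (length(vertices) == 0) abort("empty network: no nodes")
  g <- igraph::graph_from_data_frame(
    data.frame(from = a, to = b, annotation = ann, stringsAsFactors = FALSE),
    directed = FALSE, vertices = vertices
  )
  structure(list(graph = g), class = "fi_network")
}

as_igraph <- function(x) {
  if (inherits(x, "fi_network")) return(x$graph)
  if (inherits(x, "linker_subnetwork")) return(x$graph)
  if (igraph::is_igraph(x)) return(x)
  abort("cannot interpret input as a network")
}

#' Network accessors
#'
#' `network_genes()` returns the gene symbols in the network;
#' `network_edges()` returns the edge table as a tibble with each pair
#' ordered `gene_a < gene_b` and rows sorted.
#'
#' @param net an `fi_network`.
#' @return A character vector, or a tibble with columns `gene_a`, `gene_b`,
#'   `annotation`.
#' @export
network_genes <- function(net) igraph::V(as_igraph(net))$name

#' @rdname network_genes
#' @export
network_edges <- function(net) {
  g <- as_igraph(net)
  if (igraph::ecount(g) == 0) {
    return(tibble(gene_a = character(0), gene_b = character(0), annotation = character(0)))
  }
  el <- igraph::as_edgelist(g)
  ann <- igraph::E(g)$annotation %||% rep("unknown", nrow(el))
  tibble(gene_a = pmin(el[, 1], el[, 2]),
         gene_b = pmax(el[, 1], el[, 2]),
         annotation = ann) |>
    arrange(.data$gene_a, .data$gene_b)
}

#' @export
print.fi_network <- function(x, ...) {
  g <- x$graph
  cat(sprintf("<fi_network> %d genes, %d interactions, %d connected component(s)\n",
              igraph::vcount(g), igraph::ecount(g), igraph::components(g)$no))
  invisible(x)
}

#' Largest connected component of an FI network
#'
#' Returns the induced subgraph on the largest connected component, the
#' universe from which permutation nulls are drawn. Size ties are broken in
#' favour of the component containing the lexicographically smallest gene.
#'
#' @param net an `fi_network`.
#' @return An `fi_network` restricted to the largest component.
#' @export
largest_connected_component <- function(net) {
  g <- as_igraph(net)
  comp <- igraph::components(g)
  big <- which(comp$csize == max(comp$csize))
  if (length(big) > 1) {
    smallest_member <- vapply(big, function(k) {
      min(sort_c(igraph::V(g)$name[comp$membership == k]))
    }, character(1))
    big <- big[order(smallest_member)][1]
  }
  keep <- igraph::V(g)[comp$membership == big]
  structure(list(graph = igraph::induced_subgraph(g, keep)), class = "fi_network")
}

#' Map a gene list onto the network
#'
#' Computes which query genes are present in the FI network after symbol
#' upper-casing, and the coverage fraction (reported to 3 decimals).
#' Duplicated query symbols are counted once, so coverage is invariant to
#' query order and duplication.
#'
#' @param net an `fi_network`.
#' @param genes character vector of query gene symbols.
#' @return An object of class `gene_mapping` with fields `query_genes`,
#'   `in_network` and `coverage`; see [tidy.gene_mapping()].
#' @examples
#' net <- fi_network(tibble::tibble(gene_a = c("A", "B"), gene_b = c("B", "C")))
#' map_genes(net, c("a", "b", "z"))
#' @export
map_genes <- function(net, genes) {
  if (length(genes) == 0) abort("empty gene list")
  q <- unique(normalize_genes(genes))
  inn <- q[q %in% network_genes(net)]
  structure(list(
    query_genes = q,
    in_network = inn,
    coverage = round(length(inn) / length(q), 3)
  ), class = "gene_mapping")
}

#' @export
print.gene_mapping <- function(x, ...) {
  cat(sprintf("<gene_mapping> %d / %d query genes in network (coverage %.3f)\n",
              length(x$in_network), length(x$query_genes), x$coverage))
  invisible(x)
}
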