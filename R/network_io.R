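#' Read a functional-interaction network from disk
#'
#' Supported dialects: a tab-separated edge list with a header row
#' (`gene_a`, `gene_b`, optional `annotation`), Cytoscape SIF
#' (`geneA  relation  geneB`), and GraphML as written by [export_network()].
#' Rows with fewer than two gene tokens raise a parse error naming the line.
#'
#' @param path file to read.
#' @param format `"tsv"`, `"sif"` or `"graphml"`; defaults to a guess from
#'   the file extension.
#' @return An `fi_network`.
#' @export
read_network <- function(path, format = c("auto", "tsv", "sif", "graphml")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, sif = "sif", graphml = "graphml", xml = "graphml", "tsv")
  }
  switch(format,
    tsv = read_edge_list(path, sep = "\t", header = TRUE),
    sif = read_sif(path),
    graphml = read_graphml_network(path)
  )
}

read_edge_list <- function(path, sep, header) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(sprintf("empty network file: %s", path))
  start <- if (header) 2L else 1L
  if (header && length(lines) < 2) abort(sprintf("empty network file: %s", path))
  rows <- lapply(seq(start, length(lines)), function(i) {
    toks <- strsplit(lines[[i]], sep, fixed = TRUE)[[1]]
    toks <- toks[nzchar(trimws(toks))]
    if (length(toks) < 2) {
      abort(sprintf("parse error in %s at line %d: expected at least 2 gene tokens", path, i))
    }
    toks
  })
  edges <- tibble(
    gene_a = vapply(rows, `[[`, character(1), 1),
    gene_b = vapply(rows, `[[`, character(1), 2),
    annotation = vapply(rows, function(t) if (length(t) >= 3) t[[3]] else "unknown", character(1))
  )
  fi_network(edges)
}

read_sif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(sprintf("empty network file: %s", path))
  ga <- character(0); gb <- character(0); iso <- character(0)
  for (i in seq_along(lines)) {
    toks <- strsplit(trimws(lines[[i]]), "[ \t]+")[[1]]
    if (length(toks) == 1) {                 # SIF allows isolated nodes
      iso <- c(iso, toks)
    } else if (length(toks) >= 3) {          # source relation target [target ...]
      ga <- c(ga, rep(toks[1], length(toks) - 2))
      gb <- c(gb, toks[3:length(toks)])
    } else {
      abort(sprintf("parse error in %s at line %d: SIF rows need 1 or >=3 tokens", path, i))
    }
  }
  if (length(ga) == 0 && length(iso) == 0) abort(sprintf("empty network file: %s", path))
  fi_network(tibble(gene_a = ga, gene_b = gb), nodes = iso)
}

read_graphml_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nm <- igraph::vertex_attr(g, "name") %||% igraph::vertex_attr(g, "id")
  if (is.null(nm)) abort(sprintf("GraphML file %s carries no node names", path))
  igraph::V(g)$name <- normalize_genes(nm)
  if (igraph::vcount(g) == 0) abort(sprintf("empty network file: %s", path))
  el <- if (igraph::ecount(g) > 0) igraph::as_edgelist(g) else matrix(character(0), ncol = 2)
  ann <- igraph::edge_attr(g, "annotation") %||% rep("unknown", nrow(el))
  deg <- igraph::degree(g)
  net <- fi_network(
    tibble(gene_a = el[, 1], gene_b = el[, 2], annotation = ann),
    nodes = igraph::V(g)$name[deg == 0]
  )
  # carry the styling attributes back if present
  for (attr in c("role", "direction")) {
    val <- igraph::vertex_attr(g, attr)
    if (!is.null(val)) {
      idx <- match(network_genes(net), igraph::V(g)$name)
      net$graph <- igraph::set_vertex_attr(net$graph, attr, value = val[idx])
    }
  }
  net
}

#' Export a network with node roles for Cytoscape-style rendering
#'
#' Writes three files sharing a prefix: `<prefix>.sif` (relation label
#' `"fi"`), `<prefix>.nodes.tsv` with per-node `role` (`seed`/`linker`,
#' default `seed`) and `direction` (`up`/`down`/`none`, from the sign of the
#' supplied fold changes), and `<prefix>.graphml` carrying the same node
#' attributes. All rows are written in sorted order so repeated exports are
#' byte-identical.
#'
#' @param net an `fi_network` or `linker_subnetwork`.
#' @param path_prefix path prefix for the three output files.
#' @param roles named character vector mapping gene to `"seed"` or
#'   `"linker"`; unlisted genes default to `"seed"`.
#' @param direction_changes named numeric vector of signed (log) fold
#'   changes; positive maps to `up`, negative to `down`, absent to `none`.
#' @return Invisibly, a named character vector of the files written.
#' @export
export_network <- function(net, path_prefix, roles = NULL, direction_changes = NULL) {
  g <- as_igraph(net)
  genes <- igraph::V(g)$name

  check_attr_nodes <- function(x, what) {
    if (!is.null(x) && length(x) > 0) {
      if (is.null(names(x))) abort(sprintf("`%s` must be a named vector", what))
      miss <- setdiff(normalize_genes(names(x)), genes)
      if (length(miss) > 0) {
        abort(sprintf("%s refers to gene(s) not in the network: %s",
                      what, paste(sort_c(miss), collapse = ", ")))
      }
    }
  }
  check_attr_nodes(roles, "roles")
  check_attr_nodes(direction_changes, "direction_changes")

  role <- setNames(rep("seed", length(genes)), genes)
  if (!is.null(roles) && length(roles) > 0) {
    bad <- setdiff(unique(unname(roles)), c("seed", "linker"))
    if (length(bad) > 0) abort(sprintf("invalid role(s): %s", paste(bad, collapse = ", ")))
    role[normalize_genes(names(roles))] <- unname(roles)
  }
  direction <- setNames(rep("none", length(genes)), genes)
  if (!is.null(direction_changes) && length(direction_changes) > 0) {
    dc <- setNames(as.numeric(direction_changes), normalize_genes(names(direction_changes)))
    direction[names(dc)] <- ifelse(dc > 0, "up", ifelse(dc < 0, "down", "none"))
  }

  paths <- c(sif = paste0(path_prefix, ".sif"),
             nodes = paste0(path_prefix, ".nodes.tsv"),
             graphml = paste0(path_prefix, ".graphml"))

  ed <- network_edges(net)
  sif_lines <- if (nrow(ed) > 0) paste(ed$gene_a, "fi", ed$gene_b, sep = "\t") else character(0)
  iso <- genes[igraph::degree(g) == 0]
  writeLines(c(sif_lines, sort_c(iso)), paths[["sif"]])

  node_tbl <- tibble(gene = sort_c(genes)) |>
    mutate(role = unname(role[.data$gene]), direction = unname(direction[.data$gene]))
  write_tsv_det(node_tbl, paths[["nodes"]])

  g2 <- igraph::permute(g, match(igraph::V(g)$name, sort_c(genes)))
  g2 <- igraph::set_vertex_attr(g2, "role", value = unname(role[igraph::V(g2)$name]))
  g2 <- igraph::set_vertex_attr(g2, "direction", value = unname(direction[igraph::V(g2)$name]))
  if (is.null(igraph::edge_attr(g2, "annotation"))) {
    g2 <- igraph::set_edge_attr(g2, "annotation", value = rep("unknown", igraph::ecount(g2)))
  }
  igraph::write_graph(g2, paths[["graphml"]], format = "graphml")

  invisible(paths)
}
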