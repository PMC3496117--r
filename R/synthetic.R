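# Synthetic study generator: a scale-free interactome with planted dense
# modules, matched pathway annotations, and a balanced two-color dye-swap
# expression experiment in which the planted genes carry >2-fold
# resistant-vs-control effects on top of dye and array effects plus Gaussian
# noise. Every output is deterministic given the config's rng_seed.

#' Configuration of the synthetic study
#'
#' Defaults describe the desk-scale study the test-suite exercises: a
#' 400-gene scale-free interactome (preferential attachment, m = 3) with
#' three planted 25-gene modules at intra-module edge probability 0.35,
#' 15 planted differentially expressed genes per module with signed log2
#' effects of 1.5 (i.e. ~2.8-fold, comfortably past the twofold filter),
#' noise sd 0.3, and 8 balanced dye-swap arrays (16 samples).
#'
#' @param n_nodes genes in the interactome.
#' @param attachment_m edges added per node during preferential attachment.
#' @param modules data frame with columns `size` and `prob` (intra-module
#'   edge probability), one row per planted module.
#' @param n_de_per_module planted DE genes per module.
#' @param log2_effect absolute planted log2 fold change (signs random).
#' @param sigma_noise sd of the Gaussian log2 noise.
#' @param dye_effect additive log2 offset of the Cy5 channel.
#' @param array_effect_sd sd of the per-array random offset.
#' @param n_arrays number of two-color arrays; each carries one resistant
#'   and one control sample with dye assignment swapped on alternate arrays.
#' @param de_placement `"module"` plants DE genes inside the modules (the
#'   phenomenon under study: tightly linked DE genes); `"random"` scatters
#'   them uniformly as a negative control.
#' @param rng_seed integer master seed.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_nodes = 400,
                             attachment_m = 3,
                             modules = data.frame(size = c(25, 25, 25),
                                                  prob = c(0.35, 0.35, 0.35)),
                             n_de_per_module = 15,
                             log2_effect = 1.5,
                             sigma_noise = 0.3,
                             dye_effect = 0.2,
                             array_effect_sd = 0.1,
                             n_arrays = 8,
                             de_placement = c("module", "random"),
                             rng_seed = 1L) {
  de_placement <- match.arg(de_placement)
  if (!is_count(n_nodes) || !is_count(attachment_m) || !is_count(n_arrays)) {
    abort("`n_nodes`, `attachment_m` and `n_arrays` must be positive integers")
  }
  if (!is.data.frame(modules) || !all(c("size", "prob") %in% names(modules))) {
    abort("`modules` must be a data frame with columns `size` and `prob`")
  }
  if (sum(modules$size) > n_nodes) abort("module sizes exceed the network size")
  if (any(modules$prob <= 0 | modules$prob > 1)) {
    abort("infeasible intra-module density: `prob` must lie in (0, 1]")
  }
  bg_density <- 2 * attachment_m / n_nodes
  if (any(modules$prob <= bg_density)) {
    abort("infeasible density: intra-module `prob` must exceed the background density")
  }
  if (!is_count(n_de_per_module) || any(n_de_per_module > modules$size)) {
    abort("`n_de_per_module` must be a positive integer no larger than each module size")
  }
  if (sigma_noise < 0 || array_effect_sd < 0) abort("noise sds must be non-negative")
  structure(list(
    n_nodes = as.integer(n_nodes), attachment_m = as.integer(attachment_m),
    modules = as.data.frame(modules[, c("size", "prob")]),
    n_de_per_module = as.integer(n_de_per_module),
    log2_effect = log2_effect, sigma_noise = sigma_noise,
    dye_effect = dye_effect, array_effect_sd = array_effect_sd,
    n_arrays = as.integer(n_arrays), de_placement = de_placement,
    rng_seed = as.integer(rng_seed)
  ), class = "synthetic_config")
}

#' Generate a scale-free interactome with planted dense modules
#'
#' Grows a preferential-attachment backbone, then overlays each planted
#' module by adding every absent intra-module edge independently with the
#' module's edge probability (probability 1 yields a clique). Planted DE
#' genes are sampled from the modules (or uniformly, for the negative
#' control) with random effect signs.
#'
#' @param cfg a [synthetic_config()].
#' @return A list with elements `network` (an `fi_network`) and `truth`
#'   (list with `module_labels`: tibble `gene`, `module`; and `planted`:
#'   tibble `gene`, `effect` of signed log2 fold changes).
#' @export
generate_network <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$rng_seed)
  n <- cfg$n_nodes
  genes <- sprintf("G%04d", seq_len(n))
  g <- igraph::sample_pa(n, m = cfg$attachment_m, directed = FALSE)
  igraph::V(g)$name <- genes

  perm <- sample.int(n)
  offset <- 0
  labels <- rep(NA_integer_, n)
  extra_a <- character(0); extra_b <- character(0)
  for (mi in seq_len(nrow(cfg$modules))) {
    size <- cfg$modules$size[[mi]]
    prob <- cfg$modules$prob[[mi]]
    members <- sort(perm[(offset + 1):(offset + size)])
    offset <- offset + size
    labels[members] <- mi
    pairs <- combn(genes[members], 2)
    adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)[genes[members], genes[members]]
    present <- adj[cbind(pairs[1, ], pairs[2, ])] > 0
    add <- !present & runif(ncol(pairs)) < prob
    extra_a <- c(extra_a, pairs[1, add])
    extra_b <- c(extra_b, pairs[2, add])
  }
  if (length(extra_a) > 0) {
    g <- igraph::add_edges(g, rbind(extra_a, extra_b))
  }

  module_nodes <- which(!is.na(labels))
  if (cfg$de_placement == "module") {
    planted <- unlist(lapply(seq_len(nrow(cfg$modules)), function(mi) {
      sample(genes[labels == mi & !is.na(labels)], cfg$n_de_per_module)
    }))
  } else {
    planted <- sample(genes, cfg$n_de_per_module * nrow(cfg$modules))
  }
  effects <- sample(c(-1, 1), length(planted), replace = TRUE) * cfg$log2_effect

  el <- igraph::as_edgelist(g)
  net <- fi_network(tibble(gene_a = el[, 1], gene_b = el[, 2]),
                    nodes = genes)
  truth <- list(
    module_labels = tibble(gene = genes[module_nodes],
                           module = labels[module_nodes]) |>
      arrange(.data$gene),
    planted = tibble(gene = planted, effect = effects) |> arrange(.data$gene)
  )
  list(network = net, truth = truth)
}

#' Generate a matched two-color expression experiment
#'
#' Per-gene log2 intensity = baseline + effect x I(resistant) + dye offset
#' x I(Cy5) + array offset + Gaussian noise, exponentiated back to strictly
#' positive intensities. The emitted design is a balanced dye swap: every
#' array carries one resistant and one control sample, with the dye
#' assignment alternating between arrays, so the least-squares line
#' contrast is unconfounded with dye and array by construction.
#'
#' @param net the `fi_network` from [generate_network()].
#' @param truth the matching ground truth.
#' @param cfg the same [synthetic_config()].
#' @return A list with `expression` (tibble: `gene` + one column per
#'   sample) and `design` (tibble: `sample`, `line`, `dye`, `array`).
#' @export
generate_expression <- function(net, truth, cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  genes <- network_genes(net)
  miss <- setdiff(truth$planted$gene, genes)
  if (length(miss) > 0) abort("planted gene(s) not in the network")
  set.seed(derive_seed(cfg$rng_seed, 1L))

  n_arr <- cfg$n_arrays
  arrays <- sprintf("A%02d", seq_len(n_arr))
  design <- tibble(
    sample = sprintf("S%02d", seq_len(2 * n_arr)),
    line = rep(c("resistant", "control"), n_arr),
    dye = as.vector(vapply(seq_len(n_arr), function(a) {
      if (a %% 2 == 1) c("Cy5", "Cy3") else c("Cy3", "Cy5")
    }, character(2))),
    array = rep(arrays, each = 2)
  )

  effect <- setNames(rep(0, length(genes)), genes)
  effect[truth$planted$gene] <- truth$planted$effect
  baseline <- runif(length(genes), 6, 12)
  array_eff <- setNames(rnorm(n_arr, 0, cfg$array_effect_sd), arrays)

  log2mat <- outer(baseline, rep(1, nrow(design))) +
    outer(effect, as.numeric(design$line == "resistant")) +
    outer(rep(cfg$dye_effect, length(genes)), as.numeric(design$dye == "Cy5")) +
    outer(rep(1, length(genes)), array_eff[design$array]) +
    matrix(rnorm(length(genes) * nrow(design), 0, cfg$sigma_noise),
           nrow = length(genes))
  values <- 2^log2mat
  expression <- tibble(gene = genes) |>
    dplyr::bind_cols(as_tibble(setNames(as.data.frame(values), design$sample)))
  list(expression = expression, design = design)
}

#' Generate pathway annotations with known ground truth
#'
#' One pathway per planted module (exactly its member genes) plus `n_decoy`
#' random gene sets of matched sizes drawn from the whole network.
#'
#' @param net the `fi_network`.
#' @param truth the ground truth from [generate_network()].
#' @param n_decoy number of decoy pathways (default 10).
#' @param rng_seed integer seed.
#' @return A [pathway_collection()] whose background is the network genes;
#'   module pathways are named `MODULE_<i>_PATHWAY`, decoys `DECOY_<j>`.
#' @export
generate_pathways <- function(net, truth, n_decoy = 10, rng_seed = 1L) {
  genes <- network_genes(net)
  labs <- truth$module_labels
  if (nrow(labs) == 0) abort("ground truth contains no planted modules")
  set.seed(derive_seed(rng_seed, 2L))
  mods <- split(labs$gene, labs$module)
  pathways <- setNames(mods, sprintf("MODULE_%s_PATHWAY", names(mods)))
  if (n_decoy > 0) {
    sizes <- lengths(mods)[((seq_len(n_decoy) - 1) %% length(mods)) + 1]
    decoys <- lapply(sizes, function(s) sample(genes, s))
    names(decoys) <- sprintf("DECOY_%02d", seq_len(n_decoy))
    pathways <- c(pathways, decoys)
  }
  pathway_collection(pathways, background = genes)
}

#' Write the full synthetic input bundle
#'
#' Materialises one synthetic study into the exact file dialects the
#' pipeline consumes: `edges.tsv`, `expression.tsv`, `design.tsv`,
#' `pathways.gmt`, plus a `ground_truth.json` manifest of the planted
#' modules and effects.
#'
#' @param cfg a [synthetic_config()].
#' @param dir output directory (created if needed).
#' @param n_decoy decoy pathways to include (default 10).
#' @return Invisibly, a named character vector of the files written.
#' @export
simulate_inputs <- function(cfg, dir, n_decoy = 10) {
  stopifnot(inherits(cfg, "synthetic_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_network(cfg)
  ex <- generate_expression(sim$network, sim$truth, cfg)
  pc <- generate_pathways(sim$network, sim$truth, n_decoy = n_decoy,
                          rng_seed = cfg$rng_seed)
  paths <- c(network = file.path(dir, "edges.tsv"),
             expression = file.path(dir, "expression.tsv"),
             design = file.path(dir, "design.tsv"),
             pathways = file.path(dir, "pathways.gmt"),
             truth = file.path(dir, "ground_truth.json"))
  write_tsv_det(network_edges(sim$network)[, c("gene_a", "gene_b")], paths[["network"]])
  write_tsv_det(ex$expression, paths[["expression"]])
  write_tsv_det(ex$design, paths[["design"]])
  write_gmt(pc$pathways, paths[["pathways"]])
  jsonlite::write_json(list(
    config = unclass(cfg)[setdiff(names(cfg), "modules")],
    modules = cfg$modules,
    module_labels = sim$truth$module_labels,
    planted = sim$truth$planted
  ), paths[["truth"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
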