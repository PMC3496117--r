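# End-to-end orchestration: DE selection -> network mapping -> proximity ->
# core selection -> permutation test -> linkers -> MCL -> size filter ->
# enrichment -> permutation FDR -> export, with per-stage TSV outputs, a run
# manifest, and deterministic per-stage seeding derived from one master seed.

#' Pipeline run configuration
#'
#' Collects input paths (or in-memory objects) and the analysis constants:
#' twofold change, FDR 0.05 (or 0.01), 90% core coverage, 1000 permutations,
#' MCL inflation 1.6, and the 2%-of-subnetwork cluster size floor.
#'
#' @param network path to an edge-list/SIF/GraphML file, or an `fi_network`.
#' @param expression path to the expression TSV (gene column + samples), or
#'   a data frame.
#' @param design path to the design TSV (`sample`, `line`, `dye`, `array`),
#'   or a data frame.
#' @param pathways path to a GMT file, or a named list of gene sets.
#' @param out_dir output directory for stage TSVs and the manifest.
#' @param fc_min,fdr_max DE thresholds (defaults 2, 0.05).
#' @param coverage core-selection coverage (default 0.90).
#' @param min_fraction,report_min_size cluster size filters (defaults 0.02,
#'   20).
#' @param B permutations for both the proximity test and the enrichment FDR
#'   (default 1000).
#' @param inflation MCL inflation (default 1.6).
#' @param rng_seed master seed; per-stage substreams are derived from it.
#' @return A list of class `run_config`.
#' @export
pipeline_config <- function(network, expression, design, pathways, out_dir,
                            fc_min = 2, fdr_max = 0.05, coverage = 0.90,
                            min_fraction = 0.02, report_min_size = 20,
                            B = 1000, inflation = 1.6, rng_seed = 1L) {
  if (!is.numeric(fc_min) || fc_min <= 0) abort("`fc_min` must be positive")
  check_fraction(fdr_max, "fdr_max")
  check_fraction(coverage, "coverage")
  check_fraction(min_fraction, "min_fraction")
  if (!is_count(B)) abort("`B` must be a positive integer")
  if (!is.numeric(inflation) || inflation <= 1) abort("`inflation` must exceed 1")
  for (nm in c("network", "expression", "design", "pathways")) {
    x <- get(nm)
    if (is.character(x) && !file.exists(x)) abort(sprintf("%s file not found: %s", nm, x))
  }
  structure(list(network = network, expression = expression, design = design,
                 pathways = pathways, out_dir = out_dir,
                 fc_min = fc_min, fdr_max = fdr_max, coverage = coverage,
                 min_fraction = min_fraction, report_min_size = report_min_size,
                 B = as.integer(B), inflation = inflation,
                 rng_seed = as.integer(rng_seed)),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' The YAML maps field names of [pipeline_config()] to values; `overrides`
#' (e.g. from command-line flags) take precedence over the file, which takes
#' precedence over the defaults.
#'
#' @param path YAML file.
#' @param overrides named list of fields to override.
#' @return A `run_config`.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  vals <- yaml::read_yaml(path)
  vals[names(overrides)] <- overrides
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    abort(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_config, vals)
}

load_pipeline_inputs <- function(cfg) {
  net <- if (inherits(cfg$network, "fi_network")) cfg$network else read_network(cfg$network)
  expr <- if (is.data.frame(cfg$expression)) as_tibble(cfg$expression) else {
    readr::read_tsv(cfg$expression, show_col_types = FALSE, progress = FALSE)
  }
  design <- if (is.data.frame(cfg$design)) as_tibble(cfg$design) else {
    readr::read_tsv(cfg$design, show_col_types = FALSE, progress = FALSE)
  }
  pw <- if (is.list(cfg$pathways) && !is.data.frame(cfg$pathways)) cfg$pathways else read_gmt(cfg$pathways)
  list(network = net, expression = expr, design = design, pathways = pw)
}

#' Run the whole network-analysis pipeline
#'
#' Executes all stages in order, writing one TSV (or SIF/GraphML) per stage
#' into `cfg$out_dir` plus `manifest.json` (stage timings, config hash,
#' seed) and `run.log`. Stage failures abort with the stage name; outputs
#' of completed stages are kept. With the same config and seed, all TSV
#' outputs are byte-identical across runs.
#'
#' @param cfg a [pipeline_config()].
#' @return Invisibly, a list of class `fi_run` with each stage's result.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "run.log")
  cat("", file = log_path)
  log_line <- function(...) {
    cat(paste0(sprintf(...), "\n"), file = log_path, append = TRUE)
  }
  manifest_stages <- list()
  run_stage <- function(name, code, record = TRUE) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(code, error = function(e) {
      log_line("stage %s FAILED: %s", name, conditionMessage(e))
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
    dt <- proc.time()[["elapsed"]] - t0
    if (record) {
      manifest_stages[[length(manifest_stages) + 1]] <<-
        list(stage = name, seconds = round(dt, 3))
    }
    log_line("stage %s completed in %.3fs", name, dt)
    res
  }
  sseed <- function(k) derive_seed(cfg$rng_seed, k)

  inputs <- run_stage("load_inputs", load_pipeline_inputs(cfg), record = FALSE)
  net <- inputs$network

  de <- run_stage("de_selection", {
    de <- select_de_genes(inputs$expression, inputs$design,
                          fc_min = cfg$fc_min, fdr_max = cfg$fdr_max)
    write_tsv_det(as_tibble(de), file.path(cfg$out_dir, "de_table.tsv"))
    de
  })

  mapping <- run_stage("map_genes", {
    sel <- de$gene[de$selected]
    if (length(sel) == 0) abort("no gene passed the DE filters")
    m <- map_genes(net, sel)
    write_tsv_det(tidy(m), file.path(cfg$out_dir, "gene_mapping.tsv"))
    m
  })

  dm <- run_stage("pairwise_shortest_paths", {
    lcc <- largest_connected_component(net)
    seeds <- intersect(mapping$in_network, network_genes(lcc))
    if (length(seeds) < 2) abort("fewer than 2 mapped genes in the largest component")
    dm <- pairwise_shortest_paths(net, seeds)
    out <- as_tibble(as.data.frame(dm$d), rownames = "gene")
    write_tsv_det(out, file.path(cfg$out_dir, "distance_matrix.tsv"))
    dm
  })

  core <- run_stage("average_linkage_core", {
    core <- average_linkage_core(dm, coverage = cfg$coverage)
    writeLines(core$retained, file.path(cfg$out_dir, "core_genes.txt"))
    core
  })

  perm <- run_stage("permutation_test", {
    perm <- permutation_test(net, core$retained, B = cfg$B, rng_seed = sseed(11))
    write_tsv_det(glance(perm), file.path(cfg$out_dir, "permutation.tsv"))
    perm
  })

  sub <- run_stage("infer_linkers", {
    sub <- infer_linkers(net, core$retained)
    write_tsv_det(tidy(sub), file.path(cfg$out_dir, "subnetwork_nodes.tsv"))
    sub
  })

  clusters <- run_stage("mcl_cluster", {
    mcl_cluster(sub, inflation = cfg$inflation)
  })

  clusters <- run_stage("filter_clusters", {
    cs <- filter_clusters(clusters, min_fraction = cfg$min_fraction,
                          report_min_size = cfg$report_min_size)
    out <- cs$membership |>
      left_join(cs$summary, by = "cluster") |>
      arrange(.data$cluster, .data$gene)
    write_tsv_det(out, file.path(cfg$out_dir, "clusters.tsv"))
    cs
  })

  pc <- run_stage("pathway_background", {
    pathway_collection(inputs$pathways, background = network_genes(net))
  }, record = FALSE)

  retained_ids <- clusters$summary$cluster[clusters$summary$retained]
  enr <- run_stage("binomial_enrichment", {
    bind_rows(lapply(retained_ids, function(id) {
      members <- intersect(cluster_members(clusters, id), pc$background)
      if (length(members) == 0) return(NULL)
      mutate(binomial_enrichment(members, pc), cluster = id, .before = 1)
    }))
  })

  enr <- run_stage("permutation_fdr", {
    if (nrow(enr) == 0) {
      enr <- tibble(cluster = integer(0), pathway = character(0), n = integer(0),
                    k = integer(0), p0 = numeric(0), p_value = numeric(0),
                    fdr = numeric(0))
    } else {
      enr <- enr |>
        group_by(.data$cluster) |>
        mutate(fdr = permutation_fdr(.data$p_value, pc, n = .data$n[[1]],
                                     B = cfg$B,
                                     rng_seed = sseed(13 + .data$cluster[[1]]))) |>
        ungroup()
    }
    write_tsv_det(enr, file.path(cfg$out_dir, "enrichment.tsv"))
    enr
  })

  run_stage("export_network", {
    roles <- setNames(tidy(sub)$role, tidy(sub)$gene)
    dc <- setNames(de$log2fc, de$gene)
    dc <- dc[names(dc) %in% igraph::V(sub$graph)$name]
    export_network(sub, file.path(cfg$out_dir, "subnetwork"),
                   roles = roles, direction_changes = dc)
  })

  cfg_public <- unclass(cfg)
  for (nm in c("network", "expression", "design", "pathways")) {
    if (!is.character(cfg_public[[nm]])) cfg_public[[nm]] <- sprintf("<in-memory %s>", nm)
  }
  manifest <- list(
    package = "fimodules",
    version = as.character(utils::packageVersion("fimodules")),
    rng_seed = cfg$rng_seed,
    config = cfg_public,
    config_hash = rlang::hash(cfg_public),
    stages = manifest_stages
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line("run complete: %d stages", length(manifest_stages))

  invisible(structure(list(
    config = cfg, de = de, mapping = mapping, distances = dm, core = core,
    permutation = perm, subnetwork = sub, clusters = clusters,
    pathways = pc, enrichment = enr, manifest = manifest
  ), class = "fi_run"))
}

#' @export
print.fi_run <- function(x, ...) {
  cat(sprintf(paste0(
    "<fi_run> %d DE genes (%d in network, coverage %.3f)\n",
    "  core %d genes; proximity p = %.4g; subnetwork %d genes (%d linkers)\n",
    "  %d cluster(s), %d retained; %d enrichment row(s)\n"),
    sum(x$de$selected), length(x$mapping$in_network), x$mapping$coverage,
    length(x$core$retained), x$permutation$p_value,
    igraph::vcount(x$subnetwork$graph), length(x$subnetwork$linkers),
    nrow(x$clusters$summary), sum(x$clusters$summary$retained),
    nrow(x$enrichment)))
  invisible(x)
}
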