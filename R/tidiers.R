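# broom-style tidy()/glance() methods for the pipeline's result objects

#' Tidy a gene mapping
#'
#' @param x a `gene_mapping` from [map_genes()].
#' @param ... unused.
#' @return `tidy()`: tibble with one row per query gene (`gene`,
#'   `in_network`); `glance()`: one-row tibble with `n_query`,
#'   `n_in_network`, `coverage`.
#' @method tidy gene_mapping
#' @export
tidy.gene_mapping <- function(x, ...) {
  tibble(gene = x$query_genes, in_network = x$query_genes %in% x$in_network)
}

#' @rdname tidy.gene_mapping
#' @method glance gene_mapping
#' @export
glance.gene_mapping <- function(x, ...) {
  tibble(n_query = length(x$query_genes),
         n_in_network = length(x$in_network),
         coverage = x$coverage)
}

#' Tidy a DE gene table
#'
#' @param x a `de_genes` object from [select_de_genes()].
#' @param ... unused.
#' @return `tidy()`: the underlying tibble; `glance()`: one-row summary
#'   with thresholds and counts.
#' @method tidy de_genes
#' @export
tidy.de_genes <- function(x, ...) {
  as_tibble(x)
}

#' @rdname tidy.de_genes
#' @method glance de_genes
#' @export
glance.de_genes <- function(x, ...) {
  tibble(n_genes = nrow(x), n_selected = sum(x$selected),
         fc_min = attr(x, "fc_min"), fdr_max = attr(x, "fdr_max"))
}

#' Tidy a permutation proximity test
#'
#' @param x a `permutation_test` object.
#' @param ... unused.
#' @return `tidy()`: tibble of the null distribution (`permutation`,
#'   `mean_distance`); `glance()`: one-row tibble with `observed`, `B`,
#'   `p_value`, `n_seeds`, `n_excluded`, `rng_seed`.
#' @method tidy permutation_test
#' @export
tidy.permutation_test <- function(x, ...) {
  tibble(permutation = seq_len(x$B), mean_distance = x$null_values)
}

#' @rdname tidy.permutation_test
#' @method glance permutation_test
#' @export
glance.permutation_test <- function(x, ...) {
  tibble(observed = x$observed, B = x$B, p_value = x$p_value,
         n_seeds = x$n_seeds, n_excluded = x$n_excluded,
         rng_seed = x$rng_seed)
}

#' Tidy an MCL partition
#'
#' @param x an `mcl_clusters` object.
#' @param ... unused.
#' @return `tidy()`: the membership tibble joined with per-cluster size
#'   (and filter flags once [filter_clusters()] has run); `glance()`:
#'   one-row tibble with node/cluster counts, inflation and convergence.
#' @method tidy mcl_clusters
#' @export
tidy.mcl_clusters <- function(x, ...) {
  left_join(x$membership, x$summary, by = "cluster")
}

#' @rdname tidy.mcl_clusters
#' @method glance mcl_clusters
#' @export
glance.mcl_clusters <- function(x, ...) {
  tibble(n_nodes = x$n_nodes, n_clusters = nrow(x$summary),
         n_retained = if (is.null(x$summary$retained)) NA_integer_ else sum(x$summary$retained),
         largest = max(x$summary$size), inflation = x$params$inflation,
         iterations = x$iterations, converged = x$converged)
}

#' Tidy a core selection
#'
#' @param x a `core_selection` object.
#' @param ... unused.
#' @return `tidy()`: tibble of retained genes; `glance()`: one-row summary.
#' @method tidy core_selection
#' @export
tidy.core_selection <- function(x, ...) {
  tibble(gene = x$retained)
}

#' @rdname tidy.core_selection
#' @method glance core_selection
#' @export
glance.core_selection <- function(x, ...) {
  tibble(n_retained = length(x$retained), coverage = x$coverage,
         cut_height = x$cut_height)
}
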