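# Pathway enrichment: upper-tail binomial test per pathway with a
# permutation-based false discovery rate over random gene draws from the
# FI-network background.

#' Pathway collection against a background universe
#'
#' Pathway gene sets are intersected with the background (the FI-network
#' genes); pathways left empty after intersection are dropped with a
#' message.
#'
#' @param pathways named list of character vectors of gene symbols.
#' @param background character vector: the gene universe.
#' @return An object of class `pathway_collection`.
#' @export
pathway_collection <- function(pathways, background) {
  if (length(pathways) == 0) abort("no pathways supplied")
  if (is.null(names(pathways)) || any(!nzchar(names(pathways)))) {
    abort("pathways must be a named list")
  }
  background <- sort_c(unique(normalize_genes(background)))
  if (length(background) == 0) abort("empty background")
  pw <- lapply(pathways, function(g) sort_c(intersect(unique(normalize_genes(g)), background)))
  empty <- lengths(pw) == 0
  if (any(empty)) {
    inform(sprintf("dropped %d pathway(s) with no background genes", sum(empty)))
    pw <- pw[!empty]
  }
  if (length(pw) == 0) abort("no pathway overlaps the background")
  structure(list(pathways = pw, background = background), class = "pathway_collection")
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat(sprintf("<pathway_collection> %d pathway(s) over %d background genes\n",
              length(x$pathways), length(x$background)))
  invisible(x)
}

#' Read and write GMT gene-set files
#'
#' `read_gmt()` parses a GMT file (one pathway per line: name, description,
#' genes) into a named list; pass the result with a background to
#' [pathway_collection()]. `write_gmt()` writes such a list back out.
#'
#' @param path file path.
#' @param pathways named list of character vectors.
#' @param descriptions optional character vector of per-pathway
#'   descriptions (defaults to the names).
#' @return `read_gmt()`: a named list of gene vectors; `write_gmt()`: the
#'   path, invisibly.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  fgsea::gmtPathways(path)
}

#' @rdname read_gmt
#' @export
write_gmt <- function(pathways, path, descriptions = NULL) {
  descriptions <- descriptions %||% names(pathways)
  lines <- vapply(seq_along(pathways), function(i) {
    paste(c(names(pathways)[[i]], descriptions[[i]], pathways[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Binomial pathway enrichment of a gene cluster
#'
#' For each pathway covering a fraction `p0 = |pathway| / |background|` of
#' the background, the p-value is the upper-tail binomial probability
#' `P(X >= k)` of seeing at least the observed overlap `k` in `n` draws,
#' where `n` is the cluster size.
#'
#' @param cluster character vector of cluster genes (a subset of the
#'   background).
#' @param pc a [pathway_collection()].
#' @return A tibble with columns `pathway`, `n`, `k`, `p0`, `p_value`,
#'   sorted by `p_value` (ties by pathway name).
#' @examples
#' pc <- pathway_collection(list(PW = LETTERS[1:13]), background = LETTERS)
#' binomial_enrichment(LETTERS[1:10], pc)
#' @export
binomial_enrichment <- function(cluster, pc) {
  stopifnot(inherits(pc, "pathway_collection"))
  cluster <- unique(normalize_genes(cluster))
  if (length(cluster) == 0) abort("empty cluster")
  out <- setdiff(cluster, pc$background)
  if (length(out) > 0) {
    abort(sprintf("cluster gene(s) outside the background: %s",
                  paste(sort_c(out), collapse = ", ")))
  }
  n <- length(cluster)
  k <- vapply(pc$pathways, function(pw) length(intersect(cluster, pw)), integer(1))
  p0 <- lengths(pc$pathways) / length(pc$background)
  p_value <- pbinom(k - 1, size = n, prob = p0, lower.tail = FALSE)
  tibble(pathway = names(pc$pathways), n = n, k = unname(k),
         p0 = unname(p0), p_value = unname(p_value)) |>
    arrange(.data$p_value, .data$pathway)
}

#' Permutation-based false discovery rate for enrichment p-values
#'
#' For each of `B` permutations, `n` genes are drawn uniformly from the
#' background and every pathway p-value recomputed; the FDR attached to an
#' observed p-value is the mean number of null p-values at or below it per
#' permutation, divided by the number of observed p-values at or below it,
#' clipped to `[0, 1]` and monotonised by a cumulative minimum from the
#' largest p-value down.
#'
#' @param observed numeric vector of observed pathway p-values.
#' @param pc a [pathway_collection()].
#' @param n cluster size used for the observed p-values.
#' @param B number of permutations (default 1000).
#' @param rng_seed integer seed.
#' @return Numeric vector of FDR estimates aligned with `observed`.
#' @export
permutation_fdr <- function(observed, pc, n, B = 1000, rng_seed = 1L) {
  stopifnot(inherits(pc, "pathway_collection"))
  if (!is_count(B)) abort("`B` must be a positive integer")
  if (!is_count(n) || n > length(pc$background)) {
    abort("`n` must be a positive integer no larger than the background")
  }
  if (length(observed) == 0) return(numeric(0))
  if (anyNA(observed) || any(observed < 0 | observed > 1)) {
    abort("observed p-values must lie in [0, 1]")
  }

  bg_n <- length(pc$background)
  p0 <- lengths(pc$pathways) / bg_n
  # pathway x background incidence for fast overlap counting
  inc <- vapply(pc$pathways, function(pw) pc$background %in% pw,
                logical(bg_n))                       # bg_n x n_path
  set.seed(rng_seed)
  null_p <- matrix(NA_real_, nrow = B, ncol = length(pc$pathways))
  for (b in seq_len(B)) {
    draw <- sample.int(bg_n, n)
    kb <- colSums(inc[draw, , drop = FALSE])
    null_p[b, ] <- pbinom(kb - 1, size = n, prob = p0, lower.tail = FALSE)
  }

  null_sorted <- sort(as.numeric(null_p))
  obs_sorted <- sort(observed)
  fdr <- vapply(observed, function(p) {
    mean_null <- findInterval(p, null_sorted) / B    # mean #{null <= p} per permutation
    n_obs <- findInterval(p, obs_sorted)             # #{observed <= p}, >= 1
    min(1, mean_null / n_obs)
  }, numeric(1))

  ord <- order(observed, decreasing = TRUE)
  fdr[ord] <- cummin(fdr[ord])
  fdr
}

#' Enrichment of every retained cluster
#'
#' Convenience wrapper running [binomial_enrichment()] and
#' [permutation_fdr()] for each retained cluster of an MCL partition.
#'
#' @param cs an `mcl_clusters` object, filtered by [filter_clusters()]
#'   (unfiltered partitions use every cluster).
#' @param pc a [pathway_collection()].
#' @param B permutations for the FDR (default 1000).
#' @param rng_seed integer seed.
#' @return A tibble with columns `cluster`, `pathway`, `n`, `k`, `p0`,
#'   `p_value`, `fdr`.
#' @export
enrich_clusters <- function(cs, pc, B = 1000, rng_seed = 1L) {
  stopifnot(inherits(cs, "mcl_clusters"))
  ids <- if (!is.null(cs$summary$retained)) {
    cs$summary$cluster[cs$summary$retained]
  } else {
    cs$summary$cluster
  }
  if (length(ids) == 0) {
    return(tibble(cluster = integer(0), pathway = character(0), n = integer(0),
                  k = integer(0), p0 = numeric(0), p_value = numeric(0),
                  fdr = numeric(0)))
  }
  bind_rows(lapply(seq_along(ids), function(i) {
    members <- intersect(cluster_members(cs, ids[[i]]), pc$background)
    if (length(members) == 0) return(NULL)
    enr <- binomial_enrichment(members, pc)
    enr$fdr <- permutation_fdr(enr$p_value, pc, n = length(members), B = B,
                               rng_seed = derive_seed(rng_seed, i))
    mutate(enr, cluster = ids[[i]], .before = 1)
  }))
}
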