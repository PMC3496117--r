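# Differential-expression selection: per-gene factorial ANOVA on log2
# background-corrected intensities, fold-change filter, BH FDR filter.
#
# The model is main-effects only: log2(intensity) ~ line + dye + array.
# For the balanced dye-swap designs generated here, the method-of-moments
# ANOVA estimators coincide with ordinary least squares, which is what we
# fit. Factors with a single level are dropped from the model (a design with
# only one array, say, still fits).

build_design <- function(design, samples) {
  req <- c("sample", "line", "dye", "array")
  miss <- setdiff(req, names(design))
  if (length(miss) > 0) abort(sprintf("design table lacks column(s): %s", paste(miss, collapse = ", ")))
  idx <- match(samples, design$sample)
  if (anyNA(idx)) {
    abort(sprintf("sample(s) missing from design table: %s",
                  paste(samples[is.na(idx)], collapse = ", ")))
  }
  design <- design[idx, ]

  line <- as.character(design$line)
  lev <- sort_c(unique(line))
  if (!setequal(lev, c("control", "resistant"))) {
    abort("`line` must contain both levels \"control\" and \"resistant\"")
  }
  line <- factor(line, levels = c("control", "resistant"))
  if (min(table(line)) < 2) abort("need at least 2 samples per line level")

  terms <- list(line = line)
  for (nm in c("dye", "array")) {
    f <- factor(as.character(design[[nm]]))
    if (nlevels(f) >= 2) terms[[nm]] <- f
  }
  df <- as.data.frame(terms)
  X_full <- stats::model.matrix(~ ., data = df)
  red_df <- df[, setdiff(names(df), "line"), drop = FALSE]
  X_red <- if (ncol(red_df) == 0) {
    matrix(1, nrow(df), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    stats::model.matrix(~ ., data = red_df)
  }
  list(X_full = X_full, X_red = X_red, line = line)
}

# least-squares fit of all genes at once against the shared design;
# returns the line (resistant - control) contrast and its F-test p-value
fit_all_genes <- function(values, design_mats) {
  Y <- t(log2(values))                               # samples x genes
  qf <- qr(design_mats$X_full)
  qr_ <- qr(design_mats$X_red)
  n <- nrow(Y)
  df1 <- qf$rank - qr_$rank
  df2 <- n - qf$rank
  if (df2 < 1) abort("zero residual degrees of freedom: model is saturated")
  if (df1 < 1) abort("line effect is not estimable in this design")

  coef_full <- qr.coef(qf, Y)
  log2fc <- coef_full["lineresistant", ]
  rss_full <- colSums(qr.resid(qf, Y)^2)
  rss_red <- colSums(qr.resid(qr_, Y)^2)
  drss <- pmax(rss_red - rss_full, 0)

  eps <- 1e-12 * pmax(colSums(Y^2), 1)
  f <- ifelse(rss_full > eps, (drss / df1) / (rss_full / df2),
              ifelse(drss > eps, Inf, 0))
  p <- pf(f, df1, df2, lower.tail = FALSE)
  tibble(log2fc = unname(log2fc), p = unname(p))
}

check_expression <- function(expression, design) {
  if (!is.data.frame(expression) || ncol(expression) < 3) {
    abort("`expression` must be a data frame: gene column + >=2 sample columns")
  }
  samples <- names(expression)[-1]
  vals <- as.matrix(expression[, -1])
  if (!is.numeric(vals)) abort("intensity columns must be numeric")
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("intensities must be strictly positive background-corrected values")
  }
  list(genes = normalize_genes(expression[[1]]), values = vals, samples = samples)
}

#' Per-gene factorial ANOVA for a single gene
#'
#' Fits `log2(intensity) ~ line + dye + array` (main effects; single-level
#' factors dropped) and returns the least-squares resistant-vs-control
#' contrast as a log2 fold change together with the F-test p-value for the
#' line term. With two line levels and no other factors this F equals the
#' square of the equal-variance t statistic.
#'
#' @param expression data frame: first column gene symbols, remaining
#'   columns strictly positive intensities, one per sample.
#' @param design data frame with columns `sample`, `line`
#'   (`control`/`resistant`), `dye`, `array`.
#' @param gene gene symbol to fit.
#' @return A one-row tibble with columns `gene`, `log2fc`, `p`.
#' @export
fit_gene_anova <- function(expression, design, gene) {
  ex <- check_expression(expression, design)
  gene <- normalize_genes(gene)
  hit <- which(ex$genes == gene)
  if (length(hit) == 0) abort(sprintf("gene not found: %s", gene))
  dm <- build_design(design, ex$samples)
  fit <- fit_all_genes(ex$values[hit, , drop = FALSE], dm)
  if (length(hit) > 1) fit <- fit[which.max(abs(fit$log2fc)), ]   # probe collapse
  tibble(gene = gene, log2fc = fit$log2fc, p = fit$p)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up q-values controlling the false discovery rate, computed with
#' [stats::p.adjust()]. Errors on p-values outside `[0, 1]`.
#'
#' @param pvalues numeric vector of p-values.
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Select differentially expressed genes
#'
#' Runs the per-gene factorial ANOVA over every row, collapses duplicate
#' gene symbols to the probe with the largest absolute log2 fold change,
#' applies Benjamini-Hochberg FDR correction across genes, and selects genes
#' passing both the fold-change filter (`2^|log2fc| > fc_min`) and the FDR
#' filter (`q <= fdr_max`).
#'
#' @inheritParams fit_gene_anova
#' @param fc_min minimum linear fold change (default 2: "greater than
#'   twofold").
#' @param fdr_max maximum BH q-value (default 0.05; 0.01 for the stricter
#'   screen).
#' @return A tibble of class `de_genes` with columns `gene`, `log2fc`, `p`,
#'   `q`, `selected`, carrying the thresholds as attributes.
#' @examples
#' cfg <- synthetic_config(n_nodes = 60, modules = data.frame(size = 10, prob = 0.5),
#'                         n_de_per_module = 5, rng_seed = 1)
#' sim <- generate_network(cfg)
#' ex <- generate_expression(sim$network, sim$truth, cfg)
#' de <- select_de_genes(ex$expression, ex$design)
#' sum(de$selected)
#' @export
select_de_genes <- function(expression, design, fc_min = 2, fdr_max = 0.05) {
  if (!is.numeric(fc_min) || fc_min <= 0) abort("`fc_min` must be positive")
  check_fraction(fdr_max, "fdr_max")
  ex <- check_expression(expression, design)
  dm <- build_design(design, ex$samples)
  fit <- fit_all_genes(ex$values, dm)
  tbl <- tibble(gene = ex$genes, log2fc = fit$log2fc, p = fit$p) |>
    group_by(.data$gene) |>
    arrange(desc(abs(.data$log2fc)), .data$p, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    arrange(.data$gene)
  tbl <- tbl |>
    mutate(q = bh_fdr(.data$p),
           selected = 2^abs(.data$log2fc) > fc_min & .data$q <= fdr_max)
  structure(tbl, class = c("de_genes", class(tbl)),
            fc_min = fc_min, fdr_max = fdr_max)
}

#' @export
print.de_genes <- function(x, ...) {
  cat(sprintf("<de_genes> %d gene(s), %d selected (fold > %g, FDR <= %g)\n",
              nrow(x), sum(x$selected), attr(x, "fc_min"), attr(x, "fdr_max")))
  NextMethod()
}
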