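# fimodules

Gene lists produced by differential-expression screens — for example the
genes whose expression changes when a breast or ovarian carcinoma line
acquires docetaxel resistance — are hard to interpret one gene at a time.
`fimodules` asks a different question: do those genes sit close together in
a functional-interaction (FI) network, and if so, which tightly
interconnected modules do they form and which pathways are those modules
enriched for? It is written for computational biologists who have (or can
simulate) three inputs: an undirected interactome edge list, a two-color
microarray intensity matrix with its sample design, and pathway gene sets
in GMT format.

## The method

The pipeline chains seven stages, each exposed as an ordinary function that
takes and returns tibbles or small result objects:

1. **DE selection.** Per gene, a main-effects factorial ANOVA on
   log2 intensities, `log2(y) ~ line + dye + array`; the line contrast
   (resistant − control) is the log2 fold change and its F-test gives the
   p-value. Genes with linear fold change > 2 and Benjamini–Hochberg
   q ≤ 0.05 (or 0.01) become the *genes of interest*.
2. **Network mapping.** The genes of interest are intersected with the FI
   network node set (`map_genes()` reports the coverage fraction).
3. **Proximity.** Pairwise shortest-path hop counts `d(i, j)` among the
   mapped genes; average-linkage hierarchical clustering of that distance
   matrix, cut at the smallest height whose largest cluster holds ≥ 90% of
   the genes (the *interconnected core*); and a permutation test of the
   mean pairwise distance
   `p = (1 + #{null ≤ observed}) / (B + 1)` against B = 1000 random gene
   sets of equal size drawn from the largest connected component.
4. **Linkers.** A minimum spanning tree over the core's hop-distance
   complete graph, with every tree edge expanded into a concrete shortest
   path; non-seed genes on those paths are the *linkers* that glue the core
   into one subnetwork.
5. **MCL clustering.** A from-scratch Markov Cluster Algorithm (expansion
   = matrix squaring, inflation = entrywise power 1.6 with column
   renormalisation) partitions the linker-augmented subnetwork; clusters
   smaller than 2% of the subnetwork are discarded.
6. **Enrichment.** Each retained cluster of size n is scored against every
   pathway covering fraction p0 of the network by the upper-tail binomial
   probability P(X ≥ k), X ~ Bin(n, p0), k the overlap.
7. **Permutation FDR.** The binomial p-values get a false discovery rate
   estimated from 1000 random draws of n genes from the network background.

A synthetic-data module (`synthetic_config()`, `generate_network()`,
`generate_expression()`, `generate_pathways()`, `simulate_inputs()`)
generates a scale-free interactome with planted dense modules and a matched
balanced dye-swap experiment with known planted effects, so the whole chain
can be validated against ground truth.

## Worked example

```r
library(fimodules)

cfg <- synthetic_config(rng_seed = 42)        # 400-gene interactome, 3 planted modules
sim <- generate_network(cfg)
ex  <- generate_expression(sim$network, sim$truth, cfg)

de  <- select_de_genes(ex$expression, ex$design, fc_min = 2, fdr_max = 0.05)
glance(de)
#> # A tibble: 1 × 4
#>   n_genes n_selected fc_min fdr_max
#>     <int>      <int>  <dbl>   <dbl>
#> 1     400         45      2    0.05

mapping <- map_genes(sim$network, de$gene[de$selected])
mapping
#> <gene_mapping> 45 / 45 query genes in network (coverage 1.000)

dm   <- pairwise_shortest_paths(sim$network, mapping$in_network)
core <- average_linkage_core(dm, coverage = 0.90)
perm <- permutation_test(sim$network, core$retained, B = 1000, rng_seed = 42)
perm
#> <permutation_test> observed mean distance 2.397 over 45 seeds; p = 0.001998 (B = 1000)

sub <- infer_linkers(sim$network, core$retained)
cs  <- filter_clusters(mcl_cluster(sub, inflation = 1.6))
cs
#> <mcl_clusters> 45 node(s) in 3 cluster(s) (inflation 1.6, 13 iteration(s))
#>   3 cluster(s) retained at size >= 1

pc  <- generate_pathways(sim$network, sim$truth, rng_seed = 42)
enr <- enrich_clusters(cs, pc, B = 1000, rng_seed = 42)
head(dplyr::arrange(enr, p_value), 3)
#> # A tibble: 3 × 7
#>   cluster pathway              n     k     p0  p_value   fdr
#>     <int> <chr>            <int> <int>  <dbl>    <dbl> <dbl>
#> 1       1 MODULE_2_PATHWAY    15    15 0.0625 8.67e-19 0
#> 2       2 MODULE_1_PATHWAY    15    15 0.0625 8.67e-19 0.004
#> 3       3 MODULE_3_PATHWAY    15    15 0.0625 8.67e-19 0
```

Reading the output: all 45 selected genes (the 45 planted ones) map into
the network; their mean pairwise hop distance of 2.40 is smaller than in
every one of 1000 random draws but one (p ≈ 0.002), so they cluster far
more tightly than chance; MCL recovers the three planted modules exactly,
and each cluster's own module pathway dominates the enrichment table while
the decoy pathways stay flat. The planted modules here are dense enough
that no linker genes are needed; sparser seed sets acquire green-diamond
linkers, visible in the exported `subnetwork.sif` / `.graphml` /
`.nodes.tsv` files written by `run_pipeline()` or `export_network()`.

The same chain runs end to end from files:

```r
paths <- simulate_inputs(synthetic_config(rng_seed = 42), "inputs")
cfg <- pipeline_config(network = paths[["network"]], expression = paths[["expression"]],
                       design = paths[["design"]], pathways = paths[["pathways"]],
                       out_dir = "results/run", rng_seed = 42)
run_pipeline(cfg)
```

or from a shell via `inst/scripts/fimodules-cli.R` (`simulate` and `run`
subcommands).

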