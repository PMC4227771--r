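# tfhierarchy

Hierarchy and conservation analysis of cell-type transcription factor (TF)
regulatory networks.

A cell type's transcriptional program can be drawn as a directed network
over its TFs: an edge `u -> v` means TF `u` binds the promoter of the gene
encoding TF `v`.  Given a *collection* of such networks — one per cell
type, over a shared TF vocabulary — `tfhierarchy` answers, with tested,
composable functions:

* **How is each network organised?**  `vertex_sort()` collapses strongly
  connected components and classifies every TF into a **top** layer
  (regulates, never regulated), a **core** layer (both), a **bottom** layer
  (regulated only) or an isolated remainder, with leaf-removal level spans.
  `local_reaching_centrality()` / `global_reaching_centrality()` quantify
  hierarchy steepness:
  `GRC = Σ_v (C_max − LRC(v)) / (N − 1)`, where `LRC(v)` is the fraction of
  other TFs reachable from `v`.
* **Which interactions are shared, which are private?**
  `build_conservation()` counts each edge's occurrence across the
  collection; `housekeeping_edges()` (present everywhere),
  `specific_edges()` (present in exactly one cell type),
  `specific_subnetwork()` and `leave_k_out_curve()` follow from it.
* **Does local wiring identify the cell type?**  `classify_collection()`
  runs binary target-indicator features (or normalized node-degree
  profiles) through PCA, Ward clustering and the Rand index against a
  reference grouping; `random_tf_set_sweep()` repeats this over random TF
  sets.
* **Where do hubs and annotated TF classes live?**  `hubs()` (top 20% by
  degree, ties included) and `layer_enrichment_table()` (hypergeometric
  enrichment/depletion per network x layer x class).
* **Is expression of housekeeping-involved TFs stable?**
  `expression_entropy()` computes the tissue relative entropy
  `log2 T + Σ f_j log2 f_j`; `entropy_comparison()` tests groups with a
  one-sided Wilcoxon rank-sum test.
* **Do protein complexes co-regulate specific targets?**
  `complex_target_modules()` enumerates maximal bicliques (R, B): every TF
  in `B` regulated by every complex member in `R` via specific edges only;
  `hk_dense_complexes()` finds complexes densely wired by housekeeping
  edges.

Seeded generators (`generate_collection()`, `generate_expression()`,
`generate_complex_catalog()`) produce collections with *planted* layers,
backbone, specific sets, class wiring and modules, so the entire pipeline
is testable end to end without downloads.  `run_pipeline()` orchestrates
everything from a config list or YAML file and writes provenance-stamped
TSVs.

The package is aimed at computational biologists working with regulatory
network collections (e.g. footprint- or ChIP-derived TF networks across
cell types or conditions) who need the hierarchy/conservation analysis as
a reusable, validated building block.

## Worked example

Generate a 12-network collection with planted structure and run the main
analyses:

```r
library(tfhierarchy)

gen <- generate_collection(
  n_tfs = 100, n_networks = 12,
  class_sizes = c(c1 = 3, c2 = 3, c3 = 3, c4 = 3),
  layer_fractions = c(0.23, 0.67, 0.10),
  core_extra_edge_prob = 0.18, n_backbone = 150,
  n_specific_per_network = 40, marker_set_size = 5,
  class_target_overlap = 0, n_class_targets = 6, seed = 1
)
col <- gen$collection
net <- col$networks[[1]]
net
#> <tf_network> c1_01: 100 TFs, 627 interactions

layer_proportions(vertex_sort(net))
#> # A tibble: 4 × 3
#>   layer        n fraction
#>   <fct>    <int>    <dbl>
#> 1 top         23     0.23
#> 2 core        67     0.67
#> 3 bottom      10     0.1
#> 4 isolated     0     0
```

The planted layer fractions (23% top, 67% core, 10% bottom) are recovered
exactly, and the hierarchy is shallow but real:

```r
global_reaching_centrality(net)
#> [1] 0.085
```

Conservation and classification recover the planted ground truth:

```r
tab <- build_conservation(col)
nrow(housekeeping_edges(tab))             # the planted 150-edge backbone
#> [1] 150
nrow(specific_edges(tab, col, "c1_01"))   # the planted per-network edges
#> [1] 40

classify_collection(
  col, gen$truth$marker_set, k = 4,
  reference = data.frame(name = gen$truth$classes$name,
                         cluster = gen$truth$classes$class_label)
)
#> <cell_type_classification> target features, k = 4, Rand index = 1.000
```

A Rand index of 1 means the wiring of the 5 planted marker TFs alone
separates the four cell-type classes perfectly.  Hubs concentrate in the
dense core, as the hypergeometric test confirms:

```r
d <- vertex_sort(net)
hypergeom_test(net$nodes, hubs(net), d$node[d$layer == "core"], "enrichment")
#> # A tibble: 1 × 6
#>       N     K     n     x direction   p_value
#>   <int> <int> <int> <int> <chr>         <dbl>
#> 1   100    20    67    20 enrichment 0.000108
```

All 20 hubs (top 20% by out-degree) sit in the 67-TF core; the probability
of that under random placement is about 1e-4.

Fitted objects support `tidy()`, `glance()` and `autoplot()`; see the
methods vignette (`vignettes/tfhierarchy-methods.Rmd`) for the statistical
conventions, generator design and known limitations.

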