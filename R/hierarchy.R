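#' Strongly connected components of a network
#'
#' Two TFs belong to the same strongly connected component (SCC) iff each
#' reaches the other by a directed path.  Component ids are deterministic:
#' components are numbered 1, 2, ... by the lexicographically smallest member
#' symbol.
#'
#' @param net A [tf_network()].
#' @return A tibble with columns `node` and `scc_id` (integer).
#' @export
scc_membership <- function(net) {
  stopifnot_network(net)
  tibble::tibble(node = net$nodes, scc_id = unname(scc_vector(net)))
}

# integer scc id per node (named vector over net$nodes), ids ordered by
# smallest member symbol; self-loops are irrelevant to strong connectivity
scc_vector <- function(net) {
  g <- as_igraph(net, drop_self_loops = TRUE)
  memb <- igraph::components(g, mode = "strong")$membership
  memb <- memb[net$nodes]
  smallest <- tapply(names(memb), memb, min)
  new_id <- rank(smallest, ties.method = "first")
  out <- as.integer(new_id[as.character(memb)])
  names(out) <- net$nodes
  out
}

#' Three-layer hierarchy decomposition (vertex sort)
#'
#' Collapses SCCs into supernodes to obtain the condensation DAG `D`, then
#' classifies every TF into one of four layers:
#' * **core** — members of non-trivial SCCs (size >= 2), plus singleton
#'   supernodes with both in- and out-neighbours in `D` (regulate and are
#'   regulated);
#' * **top** — singleton supernodes with in-degree 0 and out-degree >= 1 in
#'   `D` (regulate without being regulated);
#' * **bottom** — singleton supernodes with out-degree 0 and in-degree >= 1
#'   (regulated only);
#' * **isolated** — TFs with no edges other than a self-loop.
#'
#' Level spans come from leaf removal on `D`: repeatedly deleting
#' out-degree-0 supernodes assigns each supernode its lowest level (the round
#' it is removed, 1 = bottom-most); the same procedure on the transposed DAG
#' in round `s` gives the highest level `H - s + 1`, where `H` is the total
#' number of rounds.  Self-loops are ignored throughout (a single
#' autoregulating TF is not a non-trivial SCC) but are retained in the
#' network for degree statistics elsewhere.
#'
#' @param net A [tf_network()].
#' @return A `hierarchy_decomposition`: a tibble with columns `node`,
#'   `layer` (factor top/core/bottom/isolated), `scc_id`, `level_low`,
#'   `level_high`, carrying attributes `height` (H) and `network`.
#' @examples
#' net <- tf_network(data.frame(r = c("a", "b"), t = c("b", "c")), "chain")
#' vertex_sort(net)
#' @export
vertex_sort <- function(net) {
  stopifnot_network(net)
  memb <- scc_vector(net)
  n_scc <- max(memb)
  scc_size <- tabulate(memb, nbins = n_scc)

  ed <- dplyr::filter(net$edges, .data$regulator != .data$target)
  su <- memb[ed$regulator]
  sv <- memb[ed$target]
  keep <- su != sv
  dag <- unique(cbind(su[keep], sv[keep]))  # condensation edges

  # longest path (in edges) from each supernode down to a sink / up to a source
  lts <- longest_path_lengths(n_scc, dag)                      # to sink
  lfs <- longest_path_lengths(n_scc, dag[, c(2, 1), drop = FALSE])  # from source
  height <- max(lts) + 1L
  level_low <- lts + 1L
  level_high <- height - lfs

  outdeg <- tabulate(dag[, 1], nbins = n_scc)
  indeg <- tabulate(dag[, 2], nbins = n_scc)
  scc_layer <- ifelse(
    scc_size >= 2, "core",
    ifelse(outdeg >= 1 & indeg == 0, "top",
      ifelse(indeg >= 1 & outdeg == 0, "bottom",
        ifelse(indeg >= 1 & outdeg >= 1, "core", "isolated"))))

  tab <- tibble::tibble(
    node = net$nodes,
    layer = factor(unname(scc_layer[memb]),
                   levels = c("top", "core", "bottom", "isolated")),
    scc_id = as.integer(unname(memb)),
    level_low = as.integer(unname(level_low[memb])),
    level_high = as.integer(unname(level_high[memb]))
  )
  structure(tab,
            class = c("hierarchy_decomposition", class(tibble::tibble())),
            height = as.integer(height), network = net$name)
}

# longest path length (edge count) from each node to a sink of the DAG given
# as a 2-column integer edge matrix; iterative DP over reverse topological
# order (Kahn peeling of out-degree-0 nodes)
longest_path_lengths <- function(n, dag) {
  dist <- integer(n)
  if (is.null(dag) || nrow(dag) == 0) return(dist)
  succ <- split(dag[, 2], factor(dag[, 1], levels = seq_len(n)))
  pred <- split(dag[, 1], factor(dag[, 2], levels = seq_len(n)))
  outdeg <- lengths(succ)
  frontier <- which(outdeg == 0L)
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (v in frontier) {
      for (p in pred[[v]]) {
        if (dist[p] < dist[v] + 1L) dist[p] <- dist[v] + 1L
        outdeg[p] <- outdeg[p] - 1L
        if (outdeg[p] == 0L) nxt <- c(nxt, p)
      }
    }
    frontier <- unique(nxt)
  }
  dist
}

#' @export
print.hierarchy_decomposition <- function(x, ...) {
  cat(sprintf("<hierarchy_decomposition> %s (height %d)\n",
              attr(x, "network"), attr(x, "height")))
  NextMethod()
}

#' Fractions of TFs per hierarchy layer
#'
#' Fractions for the top/core/bottom layers are over non-isolated TFs (so
#' they sum to 1); the isolated fraction is reported over all TFs.
#'
#' @param decomp A [vertex_sort()] decomposition.
#' @return A tibble with columns `layer`, `n`, `fraction`.
#' @export
layer_proportions <- function(decomp) {
  counts <- table(decomp$layer)
  n_non_iso <- sum(counts[c("top", "core", "bottom")])
  tibble::tibble(
    layer = factor(names(counts), levels = names(counts)),
    n = as.integer(counts),
    fraction = ifelse(
      names(counts) == "isolated",
      as.integer(counts) / max(1L, sum(counts)),
      if (n_non_iso > 0) as.integer(counts) / n_non_iso else 0
    )
  )
}

link_categories <- c("within_top", "top_core", "top_bottom",
                     "within_core", "core_top", "core_bottom",
                     "within_bottom", "bottom_any", "involving_isolated")

#' Distribution of links across hierarchy layers
#'
#' Every non-self edge is assigned to exactly one category according to the
#' layers of its endpoints; categories that are structurally impossible under
#' the layer rules (e.g. edges out of the bottom layer) are retained with
#' count 0 so fractions always sum to 1.
#'
#' @param net A [tf_network()].
#' @param decomp The decomposition computed from the same network.
#' @return A tibble with columns `category`, `n`, `fraction`.
#' @export
link_distribution <- function(net, decomp) {
  stopifnot_network(net)
  if (!setequal(net$nodes, decomp$node)) {
    stop("decomposition does not match the network's node set", call. = FALSE)
  }
  lay <- as.character(decomp$layer)
  names(lay) <- decomp$node
  ed <- dplyr::filter(net$edges, .data$regulator != .data$target)
  lu <- lay[ed$regulator]
  lv <- lay[ed$target]
  cat <- ifelse(
    lu == "isolated" | lv == "isolated", "involving_isolated",
    ifelse(lu == "bottom", "bottom_any",
      ifelse(lu == lv, paste0("within_", lu), paste0(lu, "_", lv))))
  counts <- table(factor(cat, levels = link_categories))
  total <- sum(counts)
  tibble::tibble(
    category = factor(link_categories, levels = link_categories),
    n = as.integer(counts),
    fraction = if (total > 0) as.integer(counts) / total else 0
  )
}

#' Local reaching centrality
#'
#' The LRC of a TF is the fraction of the other `N - 1` TFs it reaches by
#' directed paths.  Self-loops are ignored.
#'
#' @param net A [tf_network()] with at least two nodes.
#' @param v Optional single node symbol; if omitted, LRC of every node.
#' @return If `v` is given, a number in \[0, 1\]; otherwise a tibble with
#'   columns `node` and `lrc`.
#' @export
local_reaching_centrality <- function(net, v = NULL) {
  stopifnot_network(net)
  if (length(net$nodes) < 2) stop("network needs >= 2 nodes", call. = FALSE)
  if (!is.null(v) && !v %in% net$nodes) stop("unknown node: ", v, call. = FALSE)
  lrc <- lrc_vector(net)
  if (!is.null(v)) return(unname(lrc[v]))
  tibble::tibble(node = net$nodes, lrc = unname(lrc))
}

lrc_vector <- function(net) {
  g <- as_igraph(net, drop_self_loops = TRUE)
  d <- igraph::distances(g, mode = "out")
  reach <- rowSums(is.finite(d)) - 1L
  out <- reach / (length(net$nodes) - 1L)
  out[net$nodes]
}

#' Global reaching centrality
#'
#' `GRC = sum_v (C_max - LRC(v)) / (N - 1)` where `C_max` is the maximum LRC
#' over nodes.  A directed star has GRC 1 (steepest possible hierarchy); a
#' complete symmetric digraph has GRC 0 (flat).
#'
#' @param net A [tf_network()] with at least two nodes.
#' @return A number in \[0, 1\].
#' @export
global_reaching_centrality <- function(net) {
  stopifnot_network(net)
  if (length(net$nodes) < 2) stop("network needs >= 2 nodes", call. = FALSE)
  lrc <- lrc_vector(net)
  sum(max(lrc) - lrc) / (length(lrc) - 1L)
}

#' Check LRC ordering across layers
#'
#' In a steep hierarchy the LRC of every TF in a layer exceeds that of every
#' TF in the layers below it.  This reports all (top, core) and
#' (core, bottom) node pairs violating the strict ordering.
#'
#' @param net A [tf_network()].
#' @param decomp The decomposition of `net`.
#' @return A tibble with columns `upper`, `upper_layer`, `lower`,
#'   `lower_layer`, `lrc_upper`, `lrc_lower`; zero rows means the ordering
#'   holds.
#' @export
lrc_layer_ordering_check <- function(net, decomp) {
  stopifnot_network(net)
  lrc <- lrc_vector(net)
  lay <- as.character(decomp$layer)
  names(lay) <- decomp$node
  one_pair <- function(upper_layer, lower_layer) {
    ups <- decomp$node[lay[decomp$node] == upper_layer]
    los <- decomp$node[lay[decomp$node] == lower_layer]
    if (length(ups) == 0 || length(los) == 0) return(NULL)
    grid <- tidyr::expand_grid(upper = ups, lower = los)
    grid <- dplyr::filter(grid, lrc[.data$upper] <= lrc[.data$lower])
    if (nrow(grid) == 0) return(NULL)
    dplyr::mutate(grid,
                  upper_layer = upper_layer, lower_layer = lower_layer,
                  lrc_upper = unname(lrc[.data$upper]),
                  lrc_lower = unname(lrc[.data$lower]))
  }
  out <- dplyr::bind_rows(one_pair("top", "core"), one_pair("core", "bottom"))
  if (nrow(out) == 0) {
    out <- tibble::tibble(upper = character(), lower = character(),
                          upper_layer = character(), lower_layer = character(),
                          lrc_upper = double(), lrc_lower = double())
  }
  dplyr::select(out, "upper", "upper_layer", "lower", "lower_layer",
                "lrc_upper", "lrc_lower")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.hierarchy_decomposition <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.hierarchy_decomposition <- function(x, ...) {
  pr <- layer_proportions(x)
  tibble::tibble(
    network = attr(x, "network"),
    n_nodes = nrow(x),
    height = attr(x, "height"),
    n_top = pr$n[pr$layer == "top"],
    n_core = pr$n[pr$layer == "core"],
    n_bottom = pr$n[pr$layer == "bottom"],
    n_isolated = pr$n[pr$layer == "isolated"],
    prop_top = pr$fraction[pr$layer == "top"],
    prop_core = pr$fraction[pr$layer == "core"],
    prop_bottom = pr$fraction[pr$layer == "bottom"]
  )
}

#' @export
autoplot.hierarchy_decomposition <- function(object, ...) {
  pr <- layer_proportions(object)
  pr <- dplyr::filter(pr, .data$layer != "isolated")
  ggplot2::ggplot(pr, ggplot2::aes(x = .data$layer, y = .data$fraction,
                                   fill = .data$layer)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(
      x = NULL, y = "fraction of TFs",
      title = sprintf("Hierarchy layers: %s", attr(object, "network"))
    ) +
    ggplot2::theme_minimal()
}
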