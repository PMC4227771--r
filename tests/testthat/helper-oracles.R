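# Independent brute-force oracles used to validate the package's
# implementations.  These deliberately share no code with R/: reachability
# is done by breadth-first search over raw edge lists, condensation by
# mutual-reachability, the statistics by full enumeration.

# random directed graph as a tf_network; density p, optional self loops
rand_digraph <- function(n, p = 0.25, self_loops = FALSE) {
  nodes <- sprintf("n%02d", seq_len(n))
  grid <- expand.grid(regulator = nodes, target = nodes,
                      stringsAsFactors = FALSE)
  if (!self_loops) grid <- grid[grid$regulator != grid$target, ]
  keep <- stats::runif(nrow(grid)) < p
  tf_network(grid[keep, ], name = "rand", nodes = nodes)
}

# boolean reachability matrix (excluding trivial self-reachability) by BFS
# from every node over the raw edge list, self-loops dropped
reach_oracle <- function(net) {
  nodes <- net$nodes
  ed <- net$edges[net$edges$regulator != net$edges$target, ]
  adj <- split(ed$target, factor(ed$regulator, levels = nodes))
  reach <- matrix(FALSE, length(nodes), length(nodes),
                  dimnames = list(nodes, nodes))
  for (v in nodes) {
    seen <- character(0)
    frontier <- adj[[v]]
    while (length(frontier) > 0) {
      frontier <- setdiff(unique(frontier), seen)
      seen <- c(seen, frontier)
      frontier <- unlist(adj[frontier], use.names = FALSE)
    }
    reach[v, seen] <- TRUE
  }
  diag(reach) <- FALSE  # a node never counts itself among its reached set
  reach
}

# SCC partition from mutual reachability; ids numbered by smallest member
scc_oracle <- function(net) {
  r <- reach_oracle(net)
  nodes <- net$nodes
  mutual <- (r & t(r))
  diag(mutual) <- TRUE
  comp_of <- rep(NA_character_, length(nodes))
  names(comp_of) <- nodes
  for (v in nodes) {
    comp_of[v] <- min(nodes[mutual[v, ]])
  }
  ids <- rank(sort(unique(comp_of)), ties.method = "first")
  names(ids) <- sort(unique(comp_of))
  out <- as.integer(ids[comp_of])
  names(out) <- nodes
  out
}

# full vertex-sort oracle: condensation from the reachability oracle, layer
# rules applied literally, level spans by explicit repeated leaf deletion
vertex_sort_oracle <- function(net) {
  memb <- scc_oracle(net)
  nodes <- net$nodes
  n_scc <- max(memb)
  ed <- net$edges[net$edges$regulator != net$edges$target, ]
  su <- memb[ed$regulator]
  sv <- memb[ed$target]
  dag <- unique(cbind(su, sv)[su != sv, , drop = FALSE])

  peel <- function(edges) {
    # returns removal round per supernode by literal repeated deletion of
    # out-degree-0 supernodes
    alive <- rep(TRUE, n_scc)
    round_of <- integer(n_scc)
    r <- 0L
    while (any(alive)) {
      r <- r + 1L
      live_edges <- edges[alive[edges[, 1]] & alive[edges[, 2]], , drop = FALSE]
      has_out <- unique(live_edges[, 1])
      leaves <- which(alive & !(seq_len(n_scc) %in% has_out))
      round_of[leaves] <- r
      alive[leaves] <- FALSE
    }
    round_of
  }
  low <- peel(dag)
  s <- peel(dag[, c(2, 1), drop = FALSE])
  H <- max(low)
  high <- H - s + 1L

  scc_size <- tabulate(memb, nbins = n_scc)
  outdeg <- tabulate(dag[, 1], nbins = n_scc)
  indeg <- tabulate(dag[, 2], nbins = n_scc)
  layer_of_scc <- vapply(seq_len(n_scc), function(k) {
    if (scc_size[k] >= 2) return("core")
    if (outdeg[k] >= 1 && indeg[k] == 0) return("top")
    if (indeg[k] >= 1 && outdeg[k] == 0) return("bottom")
    if (indeg[k] >= 1 && outdeg[k] >= 1) return("core")
    "isolated"
  }, character(1))

  data.frame(node = nodes, layer = layer_of_scc[memb], scc_id = unname(memb),
             level_low = low[memb], level_high = high[memb],
             stringsAsFactors = FALSE)
}

# Rand index by direct pair enumeration
ri_oracle <- function(a, b) {
  b <- b[names(a)]
  n <- length(a)
  agree <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same1 <- a[i] == a[j]
      same2 <- b[i] == b[j]
      if (same1 == same2) agree <- agree + 1
    }
  }
  agree / choose(n, 2)
}

# hypergeometric tail by enumeration of all C(N, n) samples
hyper_oracle <- function(N, K, n, x, direction) {
  subsets <- utils::combn(N, n)
  overlaps <- colSums(subsets <= K)  # class = items 1..K
  if (direction == "enrichment") mean(overlaps >= x) else mean(overlaps <= x)
}

# Wilcoxon rank-sum p by enumeration of all C(n+m, n) group assignments
wilcox_oracle <- function(a, b, alternative) {
  pooled <- c(a, b)
  n <- length(a)
  r_obs <- rank(pooled)
  u_obs <- sum(r_obs[seq_len(n)]) - n * (n + 1) / 2
  splits <- utils::combn(length(pooled), n)
  u_all <- apply(splits, 2, function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n * (n + 1) / 2
  })
  p_less <- mean(u_all <= u_obs)
  p_greater <- mean(u_all >= u_obs)
  switch(alternative,
         less = p_less,
         greater = p_greater,
         two.sided = min(1, 2 * min(p_less, p_greater)))
}

# exhaustive Ward (minimum-variance, ward.D2 convention) agglomeration:
# evaluates every cluster pair at every step; returns merge heights and the
# k-cluster partition
ward_oracle <- function(pts, k = NULL) {
  clusters <- lapply(seq_len(nrow(pts)), function(i) i)
  heights <- numeric(0)
  snapshots <- list()
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        a <- clusters[[i]]
        b <- clusters[[j]]
        ca <- colMeans(pts[a, , drop = FALSE])
        cb <- colMeans(pts[b, , drop = FALSE])
        cost <- sqrt(2 * length(a) * length(b) / (length(a) + length(b))) *
          sqrt(sum((ca - cb)^2))
        if (cost < best[1]) best <- c(cost, i, j)
      }
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
    snapshots[[length(snapshots) + 1]] <- clusters
  }
  part_at <- function(k) {
    cl <- snapshots[[nrow(pts) - k]]
    out <- integer(nrow(pts))
    for (i in seq_along(cl)) out[cl[[i]]] <- i
    out
  }
  list(heights = heights,
       partition = if (!is.null(k)) part_at(k) else NULL,
       part_at = part_at)
}

# maximal bicliques of a named list regulator -> target set, by subset
# enumeration with literal closure checks
biclique_oracle <- function(intents, min_regulators = 2) {
  regs <- names(intents)
  out <- list()
  for (size in min_regulators:length(regs)) {
    if (size > length(regs)) break
    for (idx in asplit(utils::combn(length(regs), size), 2)) {
      R <- regs[idx]
      B <- Reduce(intersect, intents[R])
      if (length(B) == 0) next
      extent <- regs[vapply(intents, function(t) all(B %in% t), logical(1))]
      if (!setequal(extent, R)) next            # R not maximal for B
      if (!setequal(Reduce(intersect, intents[extent]), B)) next
      out[[length(out) + 1]] <- list(R = sort(R), B = sort(B))
    }
  }
  unique(out)
}

# small planted-structure collection used by several test files
small_planted <- function(seed = 42, overlap = 0) {
  generate_collection(
    n_tfs = 60, n_networks = 8,
    class_sizes = c(w = 2, x = 2, y = 2, z = 2),
    layer_fractions = c(0.2, 0.65, 0.15),
    core_extra_edge_prob = 0.08, n_backbone = 80,
    n_specific_per_network = 15, marker_set_size = 4,
    class_target_overlap = overlap, n_class_targets = 5, seed = seed
  )
}

truth_reference <- function(truth) {
  data.frame(name = truth$classes$name, cluster = truth$classes$class_label)
}

edge_key <- function(df) paste(df$regulator, df$target, sep = "\t")
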