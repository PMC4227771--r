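#' Generate a synthetic network collection with planted structure
#'
#' Produces a collection of directed TF networks that exhibits, by
#' construction, the structure the analysis pipeline assumes, with full
#' ground-truth bookkeeping:
#'
#' * nodes are partitioned into planted top/core/bottom layers per
#'   `layer_fractions`; the core is made one strongly connected component in
#'   every network by a common random Hamiltonian cycle, top nodes only emit
#'   edges (into core/bottom) and bottom nodes only receive, so
#'   [vertex_sort()] recovers the planted layers exactly;
#' * a backbone of `n_backbone` edges (including the core cycle and one
#'   attachment edge per top/bottom node) is injected into every network —
#'   the planted housekeeping set;
#' * shared "noise" edges (a pool of about
#'   `core_extra_edge_prob * n_core * (n_core - 1)` admissible pairs) are
#'   each assigned to the networks of a proper non-empty subset of classes
#'   covering 2..(n_networks - 1) networks, so they are neither
#'   housekeeping nor specific and class wiring differences extend beyond
#'   the marker set;
#' * `n_specific_per_network` edges per network are drawn from pairwise
#'   disjoint pools, each appearing in exactly one network — the planted
#'   specific sets;
#' * a marker TF set `A` of `marker_set_size` core TFs is wired to
#'   class-specific target sets (overlap between classes controlled by
#'   `class_target_overlap`; 0 = fully separable); the outgoing edges of
#'   marker TFs are excluded from the noise and specific pools so the
#'   within-class wiring of `A` is identical and classification at zero
#'   overlap is perfectly separable.
#'
#' @param n_tfs Number of TFs (nodes).
#' @param n_networks Number of networks (cell types).
#' @param class_sizes Integer vector (optionally named with class labels)
#'   summing to `n_networks`.
#' @param layer_fractions Length-3 vector (top, core, bottom) summing to 1.
#' @param core_extra_edge_prob Density parameter of the shared core noise
#'   pool.
#' @param n_backbone Number of housekeeping edges (must cover the cycle and
#'   the attachment edges).
#' @param n_specific_per_network Planted specific edges per network.
#' @param marker_set_size Size of the planted marker TF set `A`.
#' @param class_target_overlap Fraction of each class's marker-target set
#'   shared across all classes.
#' @param n_class_targets Targets per class wired to every marker TF.
#' @param seed Integer seed; the generator is a pure function of its
#'   parameters and seed.
#' @return A list with elements `collection` (a [tf_collection()]) and
#'   `truth` (planted layers, backbone, specific sets, marker set, class
#'   target sets, class labels).
#' @export
generate_collection <- function(n_tfs = 475, n_networks = 41,
                                class_sizes = c(blood = 7, cancer = 2,
                                                endothelia = 4, epithelia = 6,
                                                ESC = 1, fetal = 3,
                                                stroma = 14, viscera = 4),
                                layer_fractions = c(0.23, 0.67, 0.10),
                                core_extra_edge_prob = 0.18,
                                n_backbone = 2041,
                                n_specific_per_network = 300,
                                marker_set_size = 7,
                                class_target_overlap = 0.2,
                                n_class_targets = 10,
                                seed = 1) {
  stopifnot(abs(sum(layer_fractions) - 1) < 1e-8, n_networks >= 2)
  if (sum(class_sizes) != n_networks) {
    stop("`class_sizes` must sum to `n_networks`", call. = FALSE)
  }
  if (is.null(names(class_sizes))) {
    names(class_sizes) <- paste0("class", seq_along(class_sizes))
  }
  withr::with_seed(seed, {
    nodes <- sprintf("TF%04d", seq_len(n_tfs))
    n_top <- round(layer_fractions[1] * n_tfs)
    n_bottom <- round(layer_fractions[3] * n_tfs)
    n_core <- n_tfs - n_top - n_bottom
    if (n_core < max(3, marker_set_size + n_class_targets * length(class_sizes))) {
      stop("core too small for the requested marker/class-target geometry",
           call. = FALSE)
    }
    shuffled <- sample(nodes)
    top <- sort(shuffled[seq_len(n_top)])
    core <- sort(shuffled[n_top + seq_len(n_core)])
    bottom <- sort(shuffled[n_top + n_core + seq_len(n_bottom)])

    net_names <- sprintf("%s_%02d", rep(names(class_sizes), class_sizes),
                         unlist(lapply(class_sizes, seq_len)))
    class_label <- rep(names(class_sizes), class_sizes)

    pair_key <- function(r, t) paste(r, t, sep = "\t")

    # structural backbone: core Hamiltonian cycle + one attachment per
    # top/bottom node
    cyc <- sample(core)
    cycle_edges <- tibble::tibble(regulator = cyc,
                                  target = c(cyc[-1], cyc[1]))
    top_attach <- tibble::tibble(regulator = top,
                                 target = sample(core, n_top, replace = TRUE))
    bottom_attach <- tibble::tibble(regulator = sample(core, n_bottom, replace = TRUE),
                                    target = bottom)
    structural <- dplyr::bind_rows(cycle_edges, top_attach, bottom_attach)
    if (n_backbone < nrow(structural)) {
      stop(sprintf("`n_backbone` must be at least %d (cycle + attachments)",
                   nrow(structural)), call. = FALSE)
    }

    # marker set and class-specific target wiring (core -> core)
    marker_set <- sort(sample(core, marker_set_size))
    target_pool <- setdiff(core, marker_set)
    n_shared <- round(class_target_overlap * n_class_targets)
    shared_targets <- sample(target_pool, n_shared)
    rest_pool <- setdiff(target_pool, shared_targets)
    n_unique <- n_class_targets - n_shared
    if (length(rest_pool) < n_unique * length(class_sizes)) {
      stop("not enough core TFs for disjoint class target sets", call. = FALSE)
    }
    uniq <- sample(rest_pool, n_unique * length(class_sizes))
    class_targets <- lapply(seq_along(class_sizes), function(i) {
      sort(c(shared_targets, uniq[(i - 1) * n_unique + seq_len(n_unique)]))
    })
    names(class_targets) <- names(class_sizes)
    marker_edges <- lapply(class_targets, function(tg) {
      tidyr::expand_grid(regulator = marker_set, target = tg)
    })
    marker_keys <- unique(unlist(lapply(marker_edges, function(e)
      pair_key(e$regulator, e$target))))

    # admissible free pairs: source in top+core, sink in core+bottom, no
    # self pairs, no marker sources, minus structural and marker pairs
    sources <- setdiff(c(top, core), marker_set)
    sinks <- c(core, bottom)
    free <- tidyr::expand_grid(regulator = sources, target = sinks)
    free <- dplyr::filter(free, .data$regulator != .data$target)
    used <- c(pair_key(structural$regulator, structural$target), marker_keys)
    free <- dplyr::filter(free, !pair_key(.data$regulator, .data$target) %in% used)

    n_fill <- n_backbone - nrow(structural)
    n_pool <- round(core_extra_edge_prob * n_core * (n_core - 1))
    n_specific_total <- n_specific_per_network * n_networks

    # the density pool is core -> core: these extra edges are what make the
    # core dense (and its TFs the high-out-degree ones); backbone filler and
    # specific edges come from the full admissible set
    is_core_pair <- free$regulator %in% core & free$target %in% core
    free_core <- free[is_core_pair, ]
    if (n_pool > nrow(free_core)) {
      stop("infeasible edge budgets: requested core edges exceed admissible core pairs",
           call. = FALSE)
    }
    core_picks <- sample.int(nrow(free_core), n_pool)
    noise <- free_core[core_picks, ]
    rest <- dplyr::filter(free, !pair_key(.data$regulator, .data$target) %in%
                            pair_key(noise$regulator, noise$target))
    if (n_fill + n_specific_total > nrow(rest)) {
      stop("infeasible edge budgets: requested edges exceed admissible pairs",
           call. = FALSE)
    }
    picks <- sample.int(nrow(rest), n_fill + n_specific_total)
    fill <- rest[picks[seq_len(n_fill)], ]
    specific_all <- rest[picks[n_fill + seq_len(n_specific_total)], ]

    backbone <- dplyr::arrange(dplyr::bind_rows(structural, fill),
                               .data$regulator, .data$target)

    # shared noise: each edge occurs in the networks of a random proper,
    # non-empty subset of classes (class-structured wiring differences, so
    # the local wiring of arbitrary TFs carries the cell-type signal);
    # subsets are redrawn until the edge lands in 2..(n_networks - 1)
    # networks, so no noise edge is ever housekeeping or specific.  With a
    # single class this degenerates to random network subsets.
    n_classes <- length(class_sizes)
    draw_membership <- function() {
      if (n_classes >= 2) {
        cls_in <- sample(c(TRUE, FALSE), n_classes, replace = TRUE)
        class_label %in% names(class_sizes)[cls_in]
      } else {
        stats::runif(n_networks) < 0.5
      }
    }
    noise_member <- matrix(FALSE, nrow = max(n_pool, 0), ncol = n_networks)
    if (n_pool > 0) {
      for (i in seq_len(n_pool)) {
        repeat {
          m <- draw_membership()
          if (sum(m) >= 2 && sum(m) <= n_networks - 1) break
        }
        noise_member[i, ] <- m
      }
    }

    specific_sets <- lapply(seq_len(n_networks), function(i) {
      idx <- (i - 1) * n_specific_per_network + seq_len(n_specific_per_network)
      dplyr::arrange(specific_all[idx, ], .data$regulator, .data$target)
    })
    names(specific_sets) <- net_names

    networks <- lapply(seq_len(n_networks), function(i) {
      cls <- class_label[i]
      ed <- dplyr::bind_rows(
        backbone,
        if (n_pool > 0) noise[noise_member[, i], ] else NULL,
        specific_sets[[i]],
        marker_edges[[cls]]
      )
      tf_network(ed, name = net_names[i], nodes = nodes)
    })
    collection <- tf_collection(networks, class_label)

    # truth bookkeeping: a marker edge of a class spanning all networks is
    # housekeeping; of a singleton class it is specific to that network
    hk_truth <- backbone
    for (cls in names(class_sizes)) {
      if (class_sizes[[cls]] == n_networks) {
        hk_truth <- dplyr::bind_rows(hk_truth, marker_edges[[cls]])
      }
      if (class_sizes[[cls]] == 1) {
        nm <- net_names[class_label == cls]
        specific_sets[[nm]] <- dplyr::arrange(
          dplyr::bind_rows(specific_sets[[nm]], marker_edges[[cls]]),
          .data$regulator, .data$target)
      }
    }
    hk_truth <- dplyr::arrange(hk_truth, .data$regulator, .data$target)

    truth <- list(
      layers = tibble::tibble(
        node = nodes,
        layer = dplyr::case_when(nodes %in% top ~ "top",
                                 nodes %in% core ~ "core",
                                 TRUE ~ "bottom")
      ),
      backbone = hk_truth,
      specific = specific_sets,
      classes = tibble::tibble(name = net_names, class_label = class_label),
      marker_set = marker_set,
      class_targets = class_targets
    )
    list(collection = collection, truth = truth)
  })
}

#' Generate a synthetic gene x tissue expression matrix
#'
#' Stable genes get a constant baseline level with multiplicative log-normal
#' noise of standard deviation `noise_sd`; variable genes get tissue weights
#' drawn from a symmetric Dirichlet with small `concentration`, so their
#' mass concentrates in few tissues (the `concentration -> 0` limit is a
#' one-hot row with entropy `log2(n_tissues)`).
#'
#' @param n_genes Number of genes (ignored if `genes` is given).
#' @param n_tissues Number of tissues (default 79).
#' @param stable_fraction Fraction of genes that are stable (ignored if
#'   `stable_genes` is given).
#' @param noise_sd Log-scale noise sd for stable genes; 0 gives exactly
#'   constant rows (entropy 0).
#' @param concentration Dirichlet concentration for variable genes.
#' @param seed Integer seed.
#' @param genes Optional gene names.
#' @param stable_genes Optional character vector naming the stable genes
#'   (overrides `stable_fraction`).
#' @return A list with `expr` (an [expression_matrix()]) and `truth` (a
#'   tibble `gene`, `group` in stable/variable).
#' @export
generate_expression <- function(n_genes = 200, n_tissues = 79,
                                stable_fraction = 0.5, noise_sd = 0.05,
                                concentration = 0.05, seed = 1,
                                genes = NULL, stable_genes = NULL) {
  if (stable_fraction < 0 || stable_fraction > 1) {
    stop("`stable_fraction` must be in [0, 1]", call. = FALSE)
  }
  withr::with_seed(seed, {
    if (is.null(genes)) genes <- sprintf("G%04d", seq_len(n_genes))
    n_genes <- length(genes)
    if (is.null(stable_genes)) {
      stable_genes <- sample(genes, round(stable_fraction * n_genes))
    }
    vals <- t(vapply(genes, function(g) {
      if (g %in% stable_genes) {
        level <- stats::runif(1, 50, 150)
        level * exp(stats::rnorm(n_tissues, 0, noise_sd))
      } else {
        w <- stats::rgamma(n_tissues, shape = concentration)
        if (sum(w) == 0) w[sample.int(n_tissues, 1)] <- 1  # one-hot limit
        total <- stats::runif(1, 50, 150) * n_tissues
        total * w / sum(w)
      }
    }, numeric(n_tissues)))
    colnames(vals) <- sprintf("tissue%02d", seq_len(n_tissues))
    rownames(vals) <- genes
    list(
      expr = expression_matrix(vals),
      truth = tibble::tibble(
        gene = genes,
        group = ifelse(genes %in% stable_genes, "stable", "variable")
      )
    )
  })
}

#' Generate a complex catalog with planted complex-target modules
#'
#' Builds a protein-complex catalog over a network collection and plants
#' `n_planted_modules` regulatory complex-target modules: for each, a
#' regulator set `R` (2-3 members of one complex) and a target set `B` are
#' chosen and all `R x B` edges are injected into the designated network
#' only, guaranteeing they are specific to it.  Exact recovery is
#' guaranteed by construction: module regulators are TFs with no
#' pre-existing specific out-edges in the designated network (so their
#' common specific-target set is exactly `B`), and all other complex
#' members — and all members of unplanted complexes — are TFs that are not
#' specific-edge regulators at all.  The generator verifies the absence of
#' accidental co-targeting by re-running the detector on its own output.
#'
#' @param collection A [tf_collection()] (e.g. from
#'   [generate_collection()]).
#' @param specific_network Name of the designated network.
#' @param n_complexes Number of complexes in the catalog.
#' @param size_range Length-2 integer range of complex sizes.
#' @param n_planted_modules Number of planted modules (each in its own
#'   complex; must be <= `n_complexes`).
#' @param targets_per_module Size of each planted `B`.
#' @param seed Integer seed.
#' @return A list with `catalog` (a [complex_catalog()]), `collection` (the
#'   input collection with the module edges injected into the designated
#'   network) and `truth` (tibble `complex_id`, `regulators`, `targets`,
#'   semicolon-joined and sorted).
#' @export
generate_complex_catalog <- function(collection, specific_network,
                                     n_complexes = 20, size_range = c(3, 8),
                                     n_planted_modules = 5,
                                     targets_per_module = 3, seed = 1) {
  net <- get_network(collection, specific_network)
  if (n_planted_modules > n_complexes) {
    stop("`n_planted_modules` must be <= `n_complexes`", call. = FALSE)
  }
  withr::with_seed(seed, {
    tab <- build_conservation(collection)
    spec_now <- specific_edges(tab, collection, specific_network)
    all_keys <- paste(tab$regulator, tab$target, sep = "\t")
    spec_regs <- unique(spec_now$regulator)
    nodes <- union_nodes(collection)
    # TFs free of specific out-edges in the designated network; planted
    # module regulators and targets come from here
    quiet <- setdiff(nodes, spec_regs)
    # worst case per planted module: 3 regulators + targets, plus slack for
    # collision-skipped target candidates and one full filler draw
    need <- n_planted_modules * (3 + targets_per_module + 2) + max(size_range)
    if (length(quiet) < need) {
      stop("not enough TFs without specific out-edges to plant modules",
           call. = FALSE)
    }
    quiet <- sample(quiet)
    # take() consumes nodes reserved exclusively for planted R and B sets;
    # filler and unplanted-complex members may overlap freely across
    # complexes (they carry no specific out-edges, so they cannot form or
    # join a module) but never reuse consumed nodes
    take <- function(k) {
      out <- quiet[seq_len(k)]
      quiet <<- quiet[-seq_len(k)]
      out
    }

    # phase 1: consume every planted regulator and target set up front, so
    # no later-planted regulator can double as another complex's member
    injected <- list()
    planted <- list()
    r_sets <- list()
    for (i in seq_len(n_planted_modules)) {
      r_size <- sample(2:3, 1)
      R <- sort(take(r_size))
      # pick targets one at a time, skipping candidates whose (r, b) pair
      # already exists somewhere in the collection
      B <- character(0)
      while (length(B) < targets_per_module) {
        if (length(quiet) == 0) {
          stop("collision with existing edges exhausts admissible targets",
               call. = FALSE)
        }
        b <- take(1)
        if (!any(paste(R, b, sep = "\t") %in% all_keys)) B <- c(B, b)
      }
      B <- sort(B)
      injected[[i]] <- tidyr::expand_grid(regulator = R, target = B)
      r_sets[[i]] <- R
      planted[[i]] <- tibble::tibble(
        complex_id = sprintf("SC%04d", i),
        regulators = paste(R, collapse = ";"),
        targets = paste(B, collapse = ";")
      )
    }
    # phase 2: fillers and unplanted-complex members come from the remaining
    # never-consumed pool; they carry no specific out-edges, so they cannot
    # create or extend a module
    complexes <- list()
    for (i in seq_len(n_planted_modules)) {
      R <- r_sets[[i]]
      n_fill <- max(0, sample(size_range[1]:size_range[2], 1) - length(R))
      filler <- if (n_fill > 0) sample(quiet, n_fill) else character(0)
      complexes[[sprintf("SC%04d", i)]] <- sort(c(R, filler))
    }
    for (i in seq(n_planted_modules + 1, length.out = n_complexes - n_planted_modules)) {
      complexes[[sprintf("SC%04d", i)]] <-
        sort(sample(quiet, sample(size_range[1]:size_range[2], 1)))
    }

    new_edges <- dplyr::bind_rows(net$edges, dplyr::bind_rows(injected))
    collection$networks[[specific_network]] <-
      tf_network(new_edges, name = net$name, nodes = net$nodes)
    catalog <- complex_catalog(complexes)
    truth <- dplyr::bind_rows(planted)
    if (nrow(truth) == 0) {
      truth <- tibble::tibble(complex_id = character(), regulators = character(),
                              targets = character())
    }

    # screen for accidental co-targeting: the detector on the generated data
    # must return exactly the planted modules
    tab2 <- build_conservation(collection)
    spec2 <- specific_edges(tab2, collection, specific_network)
    found <- if (nrow(spec2) == 0) {
      tibble::tibble(complex_id = character(), regulators = character(),
                     targets = character())
    } else {
      complex_target_modules(
        specific_subnetwork(collection, specific_network, tab2), catalog)
    }
    found_key <- paste(found$complex_id, found$regulators, found$targets)
    truth_key <- paste(truth$complex_id, truth$regulators, truth$targets)
    if (!setequal(found_key, truth_key)) {
      stop("accidental co-targeting detected; choose another seed", call. = FALSE)
    }
    list(catalog = catalog, collection = collection, truth = truth)
  })
}
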