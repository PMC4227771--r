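#' Run the full multi-network analysis pipeline
#'
#' Configuration-driven orchestration: load a real collection (manifest +
#' optional gene sets / complex catalog / expression matrix) **or** generate
#' a synthetic one, then run, in order, per-network hierarchy decomposition,
#' conservation analysis, cell-type classification (marker-target features,
#' NND features and a random TF-set sweep), layer enrichment, expression
#' entropy comparison, and complex-target module detection.  Each stage can
#' be toggled off independently; disabling one stage never changes another
#' stage's numbers (stage seeds are derived independently from the run
#' seed).  Every output TSV carries a provenance header (package version,
#' seed, config hash).
#'
#' @param config A named list, or the path of a YAML file holding one.
#'   Recognised fields:
#'   * `manifest`: path of a collection manifest (real-data mode), **or**
#'     `synthetic`: a list of [generate_collection()] /
#'     [generate_expression()] / [generate_complex_catalog()] parameters
#'     (synthetic mode).  Exactly one of the two.
#'   * `gene_sets`: named list of gene-set file paths.
#'   * `complexes`: complex-catalog file path.
#'   * `expression`: expression-matrix file path.
#'   * `specific_network`: name of the focal network for specific-interaction
#'     analyses (default: first network).
#'   * `marker_set`: character vector of TFs for target-feature
#'     classification (default: synthetic truth's marker set, if any).
#'   * `stages`: named logical list over `hierarchy`, `conservation`,
#'     `classify`, `enrich`, `entropy`, `modules` (default all on where
#'     inputs allow).
#'   * `params`: `hub_fraction`, `alpha`, `k`, `n_components`, `k_max`,
#'     `n_subsets`, `min_density`, `sweep_set_size`, `sweep_draws`.
#' @param outdir Output directory.
#' @param seed Integer run seed.
#' @return Invisibly, a list of the in-memory stage results plus
#'   `files` (paths written).
#' @export
run_pipeline <- function(config, outdir, seed = 1) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("`config` must be a list or a YAML path", call. = FALSE)
  if (is.list(config$synthetic$class_sizes)) {
    # YAML maps load as named lists; generators expect a named vector
    config$synthetic$class_sizes <- unlist(config$synthetic$class_sizes)
  }
  has_real <- !is.null(config$manifest)
  has_syn <- !is.null(config$synthetic)
  if (has_real == has_syn) {
    stop("config must provide exactly one of `manifest` or `synthetic`", call. = FALSE)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- utils::modifyList(
    list(hierarchy = TRUE, conservation = TRUE, classify = TRUE,
         enrich = TRUE, entropy = TRUE, modules = TRUE),
    config$stages %||% list())
  params <- utils::modifyList(
    list(hub_fraction = 0.2, alpha = 0.05, k = 4, n_components = 7,
         k_max = 5, n_subsets = 200, min_density = 0.5,
         sweep_set_size = 7, sweep_draws = 20),
    config$params %||% list())
  cfg_hash <- rlang::hash(list(config, seed))
  files <- character(0)
  emit <- function(tab, name) {
    path <- file.path(outdir, name)
    header <- c(
      sprintf("# tfhierarchy %s", as.character(utils::packageVersion("tfhierarchy"))),
      sprintf("# seed: %d", seed),
      sprintf("# config_hash: %s", cfg_hash)
    )
    writeLines(header, path)
    readr::write_tsv(tab, path, append = TRUE, col_names = TRUE)
    files <<- c(files, path)
    path
  }
  results <- list()

  # ---- load / generate -------------------------------------------------
  truth <- NULL
  expr <- NULL
  catalog <- NULL
  gene_sets <- list()
  if (has_real) {
    collection <- read_tf_collection(config$manifest)
    if (!is.null(config$expression)) expr <- read_expression_matrix(config$expression)
    if (!is.null(config$complexes)) catalog <- read_complex_catalog(config$complexes)
    for (nm in names(config$gene_sets %||% list())) {
      gene_sets[[nm]] <- read_gene_set(config$gene_sets[[nm]], name = nm)
    }
  } else {
    syn <- config$synthetic
    gen_args <- syn[intersect(names(syn), names(formals(generate_collection)))]
    gen_args$seed <- seed
    gen <- do.call(generate_collection, gen_args)
    collection <- gen$collection
    truth <- gen$truth
    focal <- config$specific_network %||% names(collection$networks)[1]
    if (!identical(syn$modules, FALSE)) {
      cat_args <- syn[intersect(names(syn), setdiff(
        names(formals(generate_complex_catalog)), c("collection", "specific_network", "seed")))]
      cat_args$collection <- collection
      cat_args$specific_network <- focal
      cat_args$seed <- seed + 1L
      gc <- do.call(generate_complex_catalog, cat_args)
      catalog <- gc$catalog
      collection <- gc$collection
      truth$modules <- gc$truth
    }
    if (!identical(syn$expression, FALSE)) {
      # expression over the TFs plus a background of non-TF genes; TFs
      # involved in the planted backbone are the stable group
      hk_tfs <- unique(c(truth$backbone$regulator, truth$backbone$target))
      tf_genes <- union_nodes(collection)
      background <- sprintf("BG%04d", seq_along(tf_genes))
      ge <- generate_expression(genes = c(tf_genes, background),
                                stable_genes = hk_tfs, seed = seed + 2L)
      expr <- ge$expr
      truth$expression <- ge$truth
      gene_sets$hk_involved <- gene_set(hk_tfs, name = "hk_involved")
    }
  }
  focal <- config$specific_network %||% names(collection$networks)[1]
  results$collection <- collection
  results$truth <- truth
  message(sprintf("loaded %d networks (%d TFs in union)",
                  length(collection), length(union_nodes(collection))))

  # ---- hierarchy -------------------------------------------------------
  decomps <- NULL
  if (stages$hierarchy || stages$enrich) {
    decomps <- lapply(collection$networks, vertex_sort)
  }
  if (stages$hierarchy) {
    layers <- purrr::imap_dfr(decomps, function(d, nm) {
      dplyr::mutate(tidy(d), network = nm, .before = 1)
    })
    emit(layers, "hierarchy_layers.tsv")
    summary_tab <- purrr::imap_dfr(decomps, function(d, nm) {
      dplyr::mutate(glance(d),
                    grc = global_reaching_centrality(collection$networks[[nm]]))
    })
    emit(summary_tab, "hierarchy_summary.tsv")
    links <- purrr::imap_dfr(decomps, function(d, nm) {
      dplyr::mutate(link_distribution(collection$networks[[nm]], d),
                    network = nm, .before = 1)
    })
    emit(links, "link_distribution.tsv")
    results$hierarchy <- list(decompositions = decomps, summary = summary_tab,
                              links = links)
    message(sprintf("hierarchy: %d networks decomposed", length(decomps)))
  }

  # ---- conservation ----------------------------------------------------
  constab <- NULL
  if (stages$conservation || stages$enrich || stages$modules) {
    constab <- build_conservation(collection)
  }
  if (stages$conservation) {
    emit(tibble::as_tibble(constab), "conservation.tsv")
    hk <- housekeeping_edges(constab)
    emit(hk, "housekeeping_edges.tsv")
    spec <- specific_edges(constab, collection, focal)
    emit(spec, "specific_edges.tsv")
    curve <- leave_k_out_curve(collection, k_max = min(params$k_max, length(collection) - 1),
                               n_subsets = params$n_subsets, seed = seed + 11L)
    emit(tibble::as_tibble(curve), "leave_k_out.tsv")
    results$conservation <- list(table = constab, housekeeping = hk,
                                 specific = spec, curve = curve)
    message(sprintf("conservation: %d HK edges, %d edges specific to %s",
                    nrow(hk), nrow(spec), focal))
  }

  # ---- classification --------------------------------------------------
  if (stages$classify) {
    reference <- reference_partition(collection)
    marker <- config$marker_set %||% truth$marker_set
    fits <- list()
    if (!is.null(marker)) {
      fits$target <- classify_collection(collection, marker,
                                         n_components = params$n_components,
                                         k = params$k, reference = reference)
    }
    fits$nnd <- classify_collection(collection, "NND",
                                    n_components = params$n_components,
                                    k = params$k, reference = reference)
    labels <- purrr::imap_dfr(fits, function(f, nm) {
      dplyr::mutate(tidy(f), features = nm, .before = 1)
    })
    emit(labels, "classification_labels.tsv")
    emit(purrr::imap_dfr(fits, function(f, nm) {
      dplyr::mutate(glance(f), features = nm, .before = 1)
    }), "classification_summary.tsv")
    for (nm in names(fits)) {
      if (!is.null(fits[[nm]]$tree)) {
        nwk_path <- file.path(outdir, sprintf("dendrogram_%s.nwk", nm))
        export_newick(fits[[nm]], nwk_path)
        files <- c(files, nwk_path)
      }
    }
    sweep <- random_tf_set_sweep(collection, set_size = params$sweep_set_size,
                                 n_draws = params$sweep_draws, seed = seed + 21L,
                                 n_components = params$n_components,
                                 k = params$k, reference = reference)
    emit(tibble::as_tibble(sweep), "tf_set_sweep.tsv")
    results$classify <- list(fits = fits, sweep = sweep)
    message(sprintf("classification: RI = %s; sweep mean RI = %.3f",
                    paste(sprintf("%s %.3f", names(fits),
                                  vapply(fits, function(f) f$ri, numeric(1))),
                          collapse = ", "),
                    attr(sweep, "mean_ri")))
  }

  # ---- enrichment ------------------------------------------------------
  if (stages$enrich) {
    enr <- layer_enrichment_table(collection, decomps, gene_sets,
                                  hub_fraction = params$hub_fraction,
                                  alpha = params$alpha)
    emit(enr, "layer_enrichment.tsv")
    results$enrich <- enr
    message(sprintf("enrichment: %d tests", nrow(enr)))
  }

  # ---- expression entropy ----------------------------------------------
  if (stages$entropy && !is.null(expr)) {
    hk_set <- if (!is.null(gene_sets$hk_involved)) {
      gene_sets$hk_involved
    } else if (!is.null(constab)) {
      hk <- housekeeping_edges(constab)
      gene_set(unique(c(hk$regulator, hk$target)), name = "hk_involved")
    } else {
      NULL
    }
    two_groups <- !is.null(hk_set) &&
      any(gs_members(hk_set) %in% rownames(expr)) &&
      !all(rownames(expr) %in% gs_members(hk_set))
    if (!two_groups && !is.null(hk_set)) {
      message("entropy: skipped (need genes both inside and outside the HK-involved set)")
    }
    if (two_groups) {
      cmp <- entropy_comparison(expr, hk_set)
      emit(cmp$table, "expression_entropy.tsv")
      emit(glance(cmp), "entropy_comparison.tsv")
      results$entropy <- cmp
      message(sprintf("entropy: one-sided Wilcoxon p = %.3g", cmp$p_value))
    }
  }

  # ---- complex-target modules ------------------------------------------
  if (stages$modules && !is.null(catalog)) {
    spec_net <- tryCatch(specific_subnetwork(collection, focal, constab),
                         error = function(e) NULL)
    mods <- if (is.null(spec_net)) {
      tibble::tibble(complex_id = character(), regulators = character(),
                     targets = character(), n_regulators = integer(),
                     n_targets = integer(), n_edges = integer())
    } else {
      complex_target_modules(spec_net, catalog)
    }
    emit(mods, "complex_target_modules.tsv")
    hk <- housekeeping_edges(constab)
    hk_dense <- if (nrow(hk) > 0) {
      hk_dense_complexes(tf_network(hk, name = "hk"), catalog,
                         min_density = params$min_density)
    } else {
      tibble::tibble(complex_id = character(), n_members = integer(),
                     n_hk_edges = integer(), density = double(),
                     connected = logical())
    }
    emit(hk_dense, "hk_dense_complexes.tsv")
    results$modules <- list(modules = mods, hk_dense = hk_dense)
    message(sprintf("modules: %d complex-target modules, %d HK-dense complexes",
                    nrow(mods), nrow(hk_dense)))
  }

  results$files <- files
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
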