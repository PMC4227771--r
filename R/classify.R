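#' Binary target-indicator feature matrix
#'
#' Row per cell type, column per TF in the collection's union node set
#' (lexicographic order).  Entry (c, t) is 1 iff network c contains an edge
#' a -> t for some a in the TF set `A` — the local wiring pattern around `A`.
#'
#' @param collection A [tf_collection()].
#' @param A A [gene_set()] (or character vector) of TFs whose targets define
#'   the features.
#' @return A numeric matrix of class `feature_matrix` with rownames the
#'   network names; attribute `feature_type = "target"` and `tf_set`.
#' @export
target_feature_matrix <- function(collection, A) {
  members <- gs_members(A)
  if (length(members) == 0) stop("empty TF set `A`", call. = FALSE)
  cols <- union_nodes(collection)
  if (!any(members %in% cols)) {
    stop("TF set `A` is disjoint from every network", call. = FALSE)
  }
  mat <- t(vapply(collection$networks, function(net) {
    targets <- unique(net$edges$target[net$edges$regulator %in% members])
    as.numeric(cols %in% targets)
  }, numeric(length(cols))))
  dimnames(mat) <- list(names(collection$networks), cols)
  structure(mat, feature_type = "target", tf_set = members,
            class = c("feature_matrix", "matrix", "array"))
}

#' Normalized node-degree (NND) feature matrix
#'
#' Row per cell type; entry (c, t) is the total degree (in + out, a
#' self-loop counting once toward each) of TF t in network c divided by
#' twice the network's edge count, so every row sums to 1.  TFs absent from
#' a network get 0 — the global-connectivity profile used for whole-network
#' clustering.
#'
#' @param collection A [tf_collection()].
#' @return A `feature_matrix` with `feature_type = "nnd"`.
#' @export
nnd_feature_matrix <- function(collection) {
  cols <- union_nodes(collection)
  mat <- t(vapply(collection$networks, function(net) {
    if (nrow(net$edges) == 0) {
      stop("network '", net$name, "' has no edges", call. = FALSE)
    }
    deg <- table(factor(c(net$edges$regulator, net$edges$target), levels = cols))
    as.numeric(deg) / (2 * nrow(net$edges))
  }, numeric(length(cols))))
  dimnames(mat) <- list(names(collection$networks), cols)
  structure(mat, feature_type = "nnd", tf_set = character(),
            class = c("feature_matrix", "matrix", "array"))
}

#' Project feature vectors onto leading principal components
#'
#' Columns are mean-centered (not scaled) before the decomposition;
#' components are ordered by decreasing explained variance and the sign of
#' each component is fixed so that its largest-magnitude loading is
#' positive.
#'
#' @param mat A feature matrix (rows = cell types).
#' @param n_components Number of components requested; capped at
#'   `min(n_components, nrow - 1, ncol)`.
#' @return A numeric score matrix (rows x components) with attribute
#'   `explained_variance`.
#' @export
pca_project <- function(mat, n_components = 7) {
  mat <- unclass(mat)
  if (nrow(mat) < 2) stop("need >= 2 rows for PCA", call. = FALSE)
  m <- min(n_components, nrow(mat) - 1L, ncol(mat))
  pc <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  m <- min(m, ncol(pc$x))
  scores <- pc$x[, seq_len(m), drop = FALSE]
  rot <- pc$rotation[, seq_len(m), drop = FALSE]
  flip <- vapply(seq_len(m), function(j) {
    l <- rot[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(scores, 2, flip, `*`)
  structure(scores, explained_variance = (pc$sdev[seq_len(m)])^2)
}

#' Ward agglomerative clustering
#'
#' Minimum-variance (Ward) agglomeration on Euclidean distances (the
#' "ward.D2" convention); cutting the merge tree at `k` clusters yields the
#' partition.
#'
#' @param points Numeric matrix (rows = items, rownames = item names).
#' @param k Number of clusters, between 1 and the number of rows.
#' @return A list of class `ward_partition` with elements `labels` (tibble
#'   `name`, `cluster`), `k`, and `tree` (the full `hclust` merge tree).
#' @export
ward_cluster <- function(points, k) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (k < 1 || k > n) stop("`k` must be between 1 and the number of rows", call. = FALSE)
  tree <- stats::hclust(stats::dist(points), method = "ward.D2")
  cl <- stats::cutree(tree, k = k)
  structure(
    list(labels = tibble::tibble(name = rownames(points), cluster = unname(cl)),
         k = k, tree = tree),
    class = "ward_partition"
  )
}

# coerce a partition (tibble name/cluster, ward_partition, or named vector)
# to a named integer-ish vector
as_partition <- function(x) {
  if (inherits(x, "ward_partition")) x <- x$labels
  if (is.data.frame(x)) {
    out <- x$cluster
    names(out) <- x$name
    return(out)
  }
  if (is.null(names(x))) stop("partition needs item names", call. = FALSE)
  x
}

#' Rand index between two partitions
#'
#' The fraction of item pairs on which the partitions agree: placed together
#' in both or apart in both.
#'
#' @param p1,p2 Partitions over the same item set: a tibble with columns
#'   `name` and `cluster`, a [ward_cluster()] result, or a named vector.
#' @return A value in \[0, 1\]; 1 iff the partitions are equal as set
#'   partitions.
#' @export
rand_index <- function(p1, p2) {
  a <- as_partition(p1)
  b <- as_partition(p2)
  if (!setequal(names(a), names(b))) {
    stop("partitions are over different item sets", call. = FALSE)
  }
  b <- b[names(a)]
  n <- length(a)
  if (n < 2) stop("need at least two items", call. = FALSE)
  tab <- table(a, b)
  s_ij <- sum(tab^2)
  s_i <- sum(rowSums(tab)^2)
  s_j <- sum(colSums(tab)^2)
  together_both <- (s_ij - n) / 2
  apart_both <- choose(n, 2) - (s_i - n) / 2 - (s_j - n) / 2 + together_both
  (together_both + apart_both) / choose(n, 2)
}

#' Reference partition from class labels
#'
#' Builds the reference grouping used to score classifications.  By default
#' the conventional four-category reference over the eight cell classes is
#' applied (stroma + epithelia; blood; endothelia; cancer + ESC + fetal);
#' class labels not covered by `groups` each form their own category.
#'
#' @param collection A [tf_collection()].
#' @param groups Named list mapping category name -> character vector of
#'   class labels.
#' @return A tibble with columns `name` and `cluster` (category name).
#' @export
reference_partition <- function(collection,
                                groups = list(
                                  stroma_epithelia = c("stroma", "epithelia"),
                                  blood = "blood",
                                  endothelia = "endothelia",
                                  cancer_esc_fetal = c("cancer", "ESC", "fetal")
                                )) {
  lookup <- unlist(lapply(names(groups), function(g) {
    stats::setNames(rep(g, length(groups[[g]])), groups[[g]])
  }))
  cl <- collection$classes$class_label
  cat <- ifelse(cl %in% names(lookup), lookup[cl], cl)
  tibble::tibble(name = collection$classes$name, cluster = unname(cat))
}

#' Classify cell types from TF wiring
#'
#' The full pipeline: feature matrix (binary targets of a TF set `A`, or
#' NND profiles) -> PCA projection -> Ward clustering at `k` clusters ->
#' Rand index against a reference partition.
#'
#' @param collection A [tf_collection()].
#' @param features A [gene_set()] / character vector of TFs (target
#'   features), or the string `"NND"` for normalized node-degree features.
#' @param n_components Principal components kept (default 7).
#' @param k Number of clusters (default 4).
#' @param reference Reference partition; defaults to
#'   [reference_partition()] of the collection.
#' @return An object of class `cell_type_classification`: list with
#'   `labels` (tibble `name`, `class_label`, `cluster`, `reference`), `ri`,
#'   `tree` (`hclust` or `NULL` when features are degenerate), `scores`,
#'   `feature_type`, `k`, `n_components`.
#' @export
classify_collection <- function(collection, features, n_components = 7, k = 4,
                                reference = reference_partition(collection)) {
  mat <- if (identical(features, "NND")) {
    nnd_feature_matrix(collection)
  } else {
    target_feature_matrix(collection, features)
  }
  ref <- as_partition(reference)
  degenerate <- all(apply(unclass(mat), 2, function(col) length(unique(col)) == 1))
  if (degenerate) {
    warning("degenerate features: all cell types have identical feature vectors; ",
            "returning a single cluster", call. = FALSE)
    labels <- tibble::tibble(name = rownames(mat), cluster = 1L)
    tree <- NULL
    scores <- NULL
  } else {
    scores <- pca_project(mat, n_components)
    part <- ward_cluster(scores, k)
    labels <- part$labels
    tree <- part$tree
  }
  ri <- rand_index(labels, reference)
  labels <- labels |>
    dplyr::left_join(collection$classes, by = "name") |>
    dplyr::mutate(reference = unname(ref[.data$name])) |>
    dplyr::select("name", "class_label", "cluster", "reference")
  structure(
    list(labels = labels, ri = ri, tree = tree, scores = scores,
         feature_type = attr(mat, "feature_type"),
         tf_set = attr(mat, "tf_set"), k = k, n_components = n_components),
    class = "cell_type_classification"
  )
}

#' @export
print.cell_type_classification <- function(x, ...) {
  cat(sprintf(
    "<cell_type_classification> %s features, k = %d, Rand index = %.3f\n",
    x$feature_type, x$k, x$ri
  ))
  invisible(x)
}

#' @export
tidy.cell_type_classification <- function(x, ...) x$labels

#' @export
glance.cell_type_classification <- function(x, ...) {
  tibble::tibble(
    feature_type = x$feature_type,
    n_tfs = length(x$tf_set),
    n_components = x$n_components,
    k = x$k,
    rand_index = x$ri
  )
}

#' @export
autoplot.cell_type_classification <- function(object, ...) {
  if (is.null(object$scores)) {
    stop("no scores to plot (degenerate features)", call. = FALSE)
  }
  df <- tibble::tibble(
    name = rownames(object$scores),
    pc1 = object$scores[, 1],
    pc2 = if (ncol(object$scores) >= 2) object$scores[, 2] else 0
  ) |>
    dplyr::left_join(object$labels, by = "name")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pc1, y = .data$pc2,
                                   colour = factor(.data$cluster),
                                   shape = .data$reference)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = "PC1", y = "PC2", colour = "cluster",
                  shape = "reference") +
    ggplot2::theme_minimal()
}

#' Export a merge tree as Newick
#'
#' @param x A [ward_cluster()] result, a [classify_collection()] result, or
#'   an `hclust` object.
#' @param path Optional output file; if `NULL` the Newick string is
#'   returned.
#' @return The Newick string, invisibly when written to `path`.
#' @export
export_newick <- function(x, path = NULL) {
  tree <- if (inherits(x, "hclust")) x
          else if (inherits(x, "ward_partition")) x$tree
          else if (inherits(x, "cell_type_classification")) x$tree
          else stop("cannot extract an hclust tree from this object", call. = FALSE)
  if (is.null(tree)) stop("no merge tree available", call. = FALSE)
  phy <- ape::as.phylo(tree)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Classification accuracy of random TF sets
#'
#' Draws `n_draws` TF sets of size `set_size` uniformly without replacement
#' from the union regulator set of the collection and scores
#' [classify_collection()] with each — the sweep asking whether local wiring
#' around a handful of arbitrary TFs carries the cell-type signal.
#'
#' @inheritParams classify_collection
#' @param set_size Number of TFs per draw.
#' @param n_draws Number of independent draws.
#' @param seed Integer seed.
#' @return A tibble of class `tf_set_sweep` with columns `draw`, `tfs`
#'   (semicolon-joined), `rand_index`; attributes `mean_ri`, `sd_ri`.
#' @export
random_tf_set_sweep <- function(collection, set_size, n_draws = 50, seed = 1,
                                n_components = 7, k = 4,
                                reference = reference_partition(collection)) {
  regulators <- sort(unique(unlist(
    lapply(collection$networks, function(net) unique(net$edges$regulator)),
    use.names = FALSE
  )))
  if (set_size > length(regulators)) {
    stop("`set_size` exceeds the union regulator count", call. = FALSE)
  }
  out <- withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_draws), function(i) {
      tfs <- sample(regulators, set_size)
      fit <- suppressWarnings(
        classify_collection(collection, tfs, n_components = n_components,
                            k = k, reference = reference)
      )
      tibble::tibble(draw = i, tfs = paste(sort(tfs), collapse = ";"),
                     rand_index = fit$ri)
    })
  })
  structure(out, mean_ri = mean(out$rand_index), sd_ri = stats::sd(out$rand_index),
            class = c("tf_set_sweep", class(tibble::tibble())))
}
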