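#' Per-edge conservation counts across a collection
#'
#' Counts, for every distinct (regulator, target) pair occurring anywhere in
#' the collection, the number of member networks containing it.  Self-loops
#' participate like any other edge.
#'
#' @param collection A [tf_collection()].
#' @return A `conservation_table`: a tibble with columns `regulator`,
#'   `target`, `count`, carrying the attribute `n_networks`.
#' @export
build_conservation <- function(collection) {
  if (length(collection) == 0) stop("empty collection", call. = FALSE)
  all_edges <- purrr::map_dfr(collection$networks, function(net) net$edges)
  tab <- all_edges |>
    dplyr::count(.data$regulator, .data$target, name = "count") |>
    dplyr::arrange(.data$regulator, .data$target)
  structure(tab,
            class = c("conservation_table", class(tibble::tibble())),
            n_networks = length(collection))
}

#' @export
print.conservation_table <- function(x, ...) {
  cat(sprintf("<conservation_table> %d distinct edges over %d networks\n",
              nrow(x), attr(x, "n_networks")))
  NextMethod()
}

#' Housekeeping (HK) interactions
#'
#' Edges present in every network of the collection.
#'
#' @param table A [build_conservation()] table.
#' @return A tibble with columns `regulator`, `target`.
#' @export
housekeeping_edges <- function(table) {
  n <- attr(table, "n_networks")
  tibble::as_tibble(table) |>
    dplyr::filter(.data$count == n) |>
    dplyr::select("regulator", "target")
}

#' Cell-type-specific interactions
#'
#' Edges present in the named network and in no other network of the
#' collection (global occurrence count 1).
#'
#' @param table A [build_conservation()] table.
#' @param collection The [tf_collection()] the table was built from.
#' @param network Name of a member network.
#' @return A tibble with columns `regulator`, `target`.
#' @export
specific_edges <- function(table, collection, network) {
  net <- get_network(collection, network)
  once <- tibble::as_tibble(table) |>
    dplyr::filter(.data$count == 1) |>
    dplyr::select("regulator", "target")
  dplyr::inner_join(net$edges, once, by = c("regulator", "target"))
}

#' Subnetwork induced by a cell type's specific interactions
#'
#' The nodes are the endpoints of the network's specific edges; e.g. the
#' hESC-specific network induced this way is the ESCSN of the hESC analysis.
#'
#' @inheritParams specific_edges
#' @return A [tf_network()] named `<network>_specific`.
#' @export
specific_subnetwork <- function(collection, network,
                                table = build_conservation(collection)) {
  spec <- specific_edges(table, collection, network)
  if (nrow(spec) == 0) {
    stop("network '", network, "' has no specific interactions", call. = FALSE)
  }
  tf_network(spec, name = paste0(network, "_specific"))
}

#' Leave-k-out validation of the housekeeping edge set
#'
#' For each `k` in `0..k_max`, counts the interactions common to all
#' networks after leaving `k` networks out.  If the number of k-subsets is at
#' most `n_subsets` all subsets are enumerated; otherwise `n_subsets`
#' distinct subsets are sampled uniformly without replacement (seeded, so
#' the curve is reproducible).
#'
#' @param collection A [tf_collection()].
#' @param k_max Largest number of networks to leave out (< collection size).
#' @param n_subsets Number of subsets per `k` when sampling.
#' @param seed Integer seed for subset sampling.
#' @return A tibble with columns `k`, `n_subsets_used`, `exhaustive`,
#'   `mean`, `min`, `max` of the common-edge count.
#' @export
leave_k_out_curve <- function(collection, k_max = 5, n_subsets = 200, seed = 1) {
  n <- length(collection)
  if (k_max >= n) stop("`k_max` must be smaller than the collection size", call. = FALSE)
  if (k_max < 0 || n_subsets < 1) stop("invalid `k_max` or `n_subsets`", call. = FALSE)

  # edge x network membership for candidate edges (count >= n - k_max);
  # only these can be common to any retained subset
  tab <- build_conservation(collection)
  cand <- dplyr::filter(tibble::as_tibble(tab), .data$count >= n - k_max)
  key <- function(e) paste(e$regulator, e$target, sep = "\t")
  cand_keys <- key(cand)
  membership <- vapply(collection$networks, function(net) {
    cand_keys %in% key(net$edges)
  }, logical(length(cand_keys)))
  if (length(cand_keys) == 1) membership <- matrix(membership, nrow = 1)

  common_count <- function(left_out) {
    if (length(cand_keys) == 0) return(0L)
    retained <- setdiff(seq_len(n), left_out)
    sum(rowSums(membership[, retained, drop = FALSE]) == length(retained))
  }

  curve <- withr::with_seed(seed, {
    purrr::map_dfr(0:k_max, function(k) {
      n_total <- choose(n, k)
      if (n_total <= n_subsets) {
        subsets <- if (k == 0) list(integer(0)) else
          asplit(utils::combn(n, k), 2)
        exhaustive <- TRUE
      } else {
        seen <- character(0)
        subsets <- list()
        while (length(subsets) < n_subsets) {
          s <- sort(sample.int(n, k))
          id <- paste(s, collapse = ",")
          if (!id %in% seen) {
            seen <- c(seen, id)
            subsets[[length(subsets) + 1]] <- s
          }
        }
        exhaustive <- FALSE
      }
      counts <- vapply(subsets, common_count, integer(1))
      tibble::tibble(k = k, n_subsets_used = length(subsets),
                     exhaustive = exhaustive,
                     mean = mean(counts), min = min(counts), max = max(counts))
    })
  })
  structure(curve, class = c("leave_k_out", class(tibble::tibble())))
}

#' @export
autoplot.leave_k_out <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$min, ymax = .data$max),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "networks left out (k)", y = "common interactions") +
    ggplot2::theme_minimal()
}
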