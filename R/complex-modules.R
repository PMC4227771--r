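#' Regulatory complex-target modules
#'
#' For each protein complex, finds sets `R` of two or more complex members
#' and target sets `B` such that every TF in `B` is regulated by every TF in
#' `R` through the supplied cell-type-specific network.  A module is a
#' *maximal biclique* (closed concept) in the bipartite regulator -> target
#' relation restricted to complex members: `B` is the exact common target
#' set of `R`, and `R` is the full set of present members targeting all of
#' `B`.  One module is reported per complex even if another complex shares
#' the same regulators.
#'
#' @param specific_net A [tf_network()] of cell-type-specific interactions
#'   (see [specific_subnetwork()]).
#' @param catalog A [complex_catalog()].
#' @param min_regulators Minimum size of `R` (default 2).
#' @param maximal If `FALSE`, report every regulator subset of size >=
#'   `min_regulators` with a non-empty common target set (report-all mode;
#'   only feasible for small complexes).
#' @return A tibble with columns `complex_id`, `regulators`
#'   (semicolon-joined, sorted), `targets` (semicolon-joined, sorted),
#'   `n_regulators`, `n_targets`, `n_edges`, sorted by complex id then
#'   decreasing `n_regulators` then regulators.
#' @export
complex_target_modules <- function(specific_net, catalog, min_regulators = 2,
                                   maximal = TRUE) {
  if (!inherits(catalog, "complex_catalog")) catalog <- complex_catalog(catalog)
  stopifnot_network(specific_net)
  targets_by_reg <- split(specific_net$edges$target, specific_net$edges$regulator)

  one_complex <- function(id) {
    present <- intersect(catalog[[id]], names(targets_by_reg))
    if (length(present) < min_regulators) return(NULL)
    intents <- lapply(targets_by_reg[present], unique)
    if (maximal) {
      concepts <- closed_target_sets(intents)
    } else {
      if (length(present) > 20) {
        stop("report-all mode is limited to complexes with <= 20 present members",
             call. = FALSE)
      }
      concepts <- all_subset_concepts(intents, min_regulators)
    }
    rows <- purrr::map_dfr(concepts, function(cc) {
      if (length(cc$R) < min_regulators || length(cc$B) == 0) return(NULL)
      tibble::tibble(
        complex_id = id,
        regulators = paste(sort(cc$R), collapse = ";"),
        targets = paste(sort(cc$B), collapse = ";"),
        n_regulators = length(cc$R),
        n_targets = length(cc$B),
        n_edges = length(cc$R) * length(cc$B)
      )
    })
    if (is.null(rows) || nrow(rows) == 0) NULL else dplyr::distinct(rows)
  }

  out <- purrr::map_dfr(names(catalog), one_complex)
  if (nrow(out) == 0) {
    return(tibble::tibble(complex_id = character(), regulators = character(),
                          targets = character(), n_regulators = integer(),
                          n_targets = integer(), n_edges = integer()))
  }
  dplyr::arrange(out, .data$complex_id, dplyr::desc(.data$n_regulators),
                 .data$regulators)
}

# closed concepts of the bipartite relation given as a named list
# regulator -> target set: the family of target-set intersections closed
# under pairwise intersection; for each closed B the extent R is every
# regulator whose targets contain B
closed_target_sets <- function(intents) {
  fam <- unique(lapply(intents, sort))
  repeat {
    new <- list()
    keys <- vapply(fam, paste, character(1), collapse = "\r")
    for (i in seq_along(fam)) {
      for (j in seq_along(intents)) {
        inter <- sort(intersect(fam[[i]], intents[[j]]))
        if (length(inter) == 0) next
        k <- paste(inter, collapse = "\r")
        if (!k %in% keys) {
          new[[length(new) + 1]] <- inter
          keys <- c(keys, k)
        }
      }
    }
    if (length(new) == 0) break
    fam <- c(fam, new)
  }
  lapply(fam, function(B) {
    R <- names(intents)[vapply(intents, function(t) all(B %in% t), logical(1))]
    # keep only closed pairs: B must be the exact common target set of R
    common <- sort(Reduce(intersect, intents[R]))
    if (!identical(common, B)) return(list(R = character(), B = character()))
    list(R = R, B = B)
  })
}

# every regulator subset with its common target set (report-all mode)
all_subset_concepts <- function(intents, min_regulators) {
  regs <- names(intents)
  out <- list()
  for (size in min_regulators:length(regs)) {
    for (idx in asplit(utils::combn(length(regs), size), 2)) {
      R <- regs[idx]
      B <- sort(Reduce(intersect, intents[R]))
      if (length(B) > 0) out[[length(out) + 1]] <- list(R = R, B = B)
    }
  }
  out
}

#' Protein complexes densely wired by housekeeping interactions
#'
#' For each complex with at least `min_members` members present in the
#' housekeeping network, computes the internal link density (ordered
#' member pairs carrying an HK edge, self-loops excluded, over `m(m-1)`)
#' and keeps complexes that are dense (`density >= min_density`) and whose
#' members' HK subgraph is weakly connected.
#'
#' @param hk_net A [tf_network()] induced by [housekeeping_edges()].
#' @param catalog A [complex_catalog()].
#' @param min_members Minimum number of members present (default 3).
#' @param min_density Density threshold in (0, 1]; "highly connected" is not
#'   a canonical cutoff, so this is a required, reported parameter
#'   (default 0.5).
#' @return A tibble with columns `complex_id`, `n_members`, `n_hk_edges`,
#'   `density`, `connected`, sorted by decreasing density.
#' @export
hk_dense_complexes <- function(hk_net, catalog, min_members = 3,
                               min_density = 0.5) {
  if (!inherits(catalog, "complex_catalog")) catalog <- complex_catalog(catalog)
  stopifnot_network(hk_net)
  rows <- purrr::map_dfr(names(catalog), function(id) {
    members <- intersect(catalog[[id]], hk_net$nodes)
    m <- length(members)
    if (m < min_members) return(NULL)
    internal <- dplyr::filter(hk_net$edges,
                              .data$regulator %in% members,
                              .data$target %in% members,
                              .data$regulator != .data$target)
    dens <- nrow(internal) / (m * (m - 1))
    connected <- if (nrow(internal) == 0) {
      FALSE
    } else {
      g <- igraph::graph_from_data_frame(internal, directed = TRUE,
                                         vertices = members)
      igraph::is_connected(g, mode = "weak")
    }
    tibble::tibble(complex_id = id, n_members = m,
                   n_hk_edges = nrow(internal), density = dens,
                   connected = connected)
  })
  if (nrow(rows) == 0) {
    return(tibble::tibble(complex_id = character(), n_members = integer(),
                          n_hk_edges = integer(), density = double(),
                          connected = logical()))
  }
  rows |>
    dplyr::filter(.data$density >= min_density, .data$connected) |>
    dplyr::arrange(dplyr::desc(.data$density), .data$complex_id)
}
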