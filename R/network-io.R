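#' Directed TF regulatory network
#'
#' A `tf_network` is a named directed graph over transcription-factor (TF)
#' symbols.  Edges are ordered (regulator, target) pairs; self-loops
#' (autoregulation) are permitted, duplicate pairs are collapsed.
#'
#' @param edges A data frame whose first two columns are the regulator and
#'   target symbols (extra columns are ignored), or a two-column character
#'   matrix.
#' @param name Text identifier for the network (e.g. the cell type).
#' @param nodes Optional character vector of additional node symbols that
#'   carry no edges (they are kept as isolated nodes).
#' @return An object of class `tf_network` with fields `name`, `nodes`
#'   (lexicographically sorted) and `edges` (a sorted two-column tibble).
#' @examples
#' net <- tf_network(data.frame(regulator = "SOX2", target = "NANOG"), "hESC")
#' net
#' @export
tf_network <- function(edges, name = "network", nodes = character()) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2) {
    stop("`edges` must have at least two columns (regulator, target)", call. = FALSE)
  }
  reg <- trimws(as.character(edges[[1]]))
  tar <- trimws(as.character(edges[[2]]))
  keep <- !(is.na(reg) | is.na(tar) | reg == "" | tar == "")
  tab <- tibble::tibble(regulator = reg[keep], target = tar[keep]) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$regulator, .data$target)
  all_nodes <- sort(unique(c(tab$regulator, tab$target, trimws(as.character(nodes)))))
  structure(
    list(name = as.character(name)[1], nodes = all_nodes, edges = tab),
    class = "tf_network"
  )
}

#' @export
print.tf_network <- function(x, ...) {
  cat(sprintf(
    "<tf_network> %s: %d TFs, %d interactions\n",
    x$name, length(x$nodes), nrow(x$edges)
  ))
  invisible(x)
}

#' @export
format.tf_network <- function(x, ...) {
  sprintf("<tf_network> %s (%d nodes, %d edges)", x$name, length(x$nodes), nrow(x$edges))
}

n_nodes <- function(net) length(net$nodes)
n_edges <- function(net) nrow(net$edges)

stopifnot_network <- function(net) {
  if (!inherits(net, "tf_network")) stop("expected a `tf_network`", call. = FALSE)
  if (length(net$nodes) == 0) stop("empty network", call. = FALSE)
  invisible(net)
}

#' Convert a tf_network to an igraph graph
#'
#' @param net A [tf_network()].
#' @param drop_self_loops Remove self-loops (u,u) before conversion.
#' @return An `igraph` directed graph whose vertex names are the TF symbols.
#' @export
as_igraph <- function(net, drop_self_loops = FALSE) {
  stopifnot_network(net)
  ed <- net$edges
  if (drop_self_loops) ed <- dplyr::filter(ed, .data$regulator != .data$target)
  igraph::graph_from_data_frame(ed, directed = TRUE, vertices = net$nodes)
}

#' Collection of per-cell-type networks
#'
#' Bundles an ordered list of [tf_network()] objects with one class label per
#' network (the unit that all cross-network analyses consume).
#'
#' @param networks List of `tf_network` objects with unique names.
#' @param class_label Character vector of class tags, one per network (e.g.
#'   blood, cancer, endothelia, epithelia, ESC, fetal, stroma, viscera).
#' @return An object of class `tf_collection` with fields `networks` (named
#'   list) and `classes` (tibble with columns `name`, `class_label`).
#' @export
tf_collection <- function(networks, class_label) {
  nms <- vapply(networks, function(n) n$name, character(1))
  if (anyDuplicated(nms)) {
    stop("duplicate network name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  if (length(class_label) != length(networks)) {
    stop("`class_label` must have one entry per network", call. = FALSE)
  }
  names(networks) <- nms
  structure(
    list(
      networks = networks,
      classes = tibble::tibble(name = nms, class_label = as.character(class_label))
    ),
    class = "tf_collection"
  )
}

#' @export
print.tf_collection <- function(x, ...) {
  cat(sprintf(
    "<tf_collection> %d networks, %d classes, %d TFs in union\n",
    length(x$networks), dplyr::n_distinct(x$classes$class_label),
    length(union_nodes(x))
  ))
  invisible(x)
}

#' @export
length.tf_collection <- function(x) length(x$networks)

#' Union node set of a collection
#'
#' @param collection A [tf_collection()].
#' @return Lexicographically sorted character vector of all TF symbols
#'   occurring in any member network.
#' @export
union_nodes <- function(collection) {
  sort(unique(unlist(lapply(collection$networks, function(n) n$nodes), use.names = FALSE)))
}

get_network <- function(collection, name) {
  if (!name %in% names(collection$networks)) {
    stop("unknown network name: ", name, call. = FALSE)
  }
  collection$networks[[name]]
}

#' Gene set
#'
#' @param members Character vector of TF symbols (whitespace-stripped,
#'   case preserved).
#' @param name Text identifier.
#' @return An object of class `gene_set`: the unique member symbols with a
#'   `name` attribute.
#' @export
gene_set <- function(members, name = "gene_set") {
  members <- unique(trimws(as.character(members)))
  members <- members[members != ""]
  structure(members, name = as.character(name)[1], class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d symbols\n", attr(x, "name"), length(x)))
  invisible(x)
}

gs_members <- function(x) {
  if (inherits(x, "gene_set")) as.character(unclass(x)) else as.character(x)
}

#' Protein-complex catalog
#'
#' @param complexes Named list: complex id -> character vector of member
#'   protein symbols (each complex must have at least one member).
#' @return An object of class `complex_catalog`.
#' @export
complex_catalog <- function(complexes) {
  if (length(complexes) == 0) stop("empty complex catalog", call. = FALSE)
  if (is.null(names(complexes)) || any(names(complexes) == "")) {
    stop("every complex needs an id", call. = FALSE)
  }
  if (anyDuplicated(names(complexes))) {
    stop("duplicate complex id(s)", call. = FALSE)
  }
  complexes <- lapply(complexes, function(m) unique(trimws(as.character(m))))
  sizes <- lengths(complexes)
  if (any(sizes == 0)) {
    stop("complex with 0 members: ",
         paste(names(complexes)[sizes == 0], collapse = ", "), call. = FALSE)
  }
  structure(complexes, class = "complex_catalog")
}

#' @export
print.complex_catalog <- function(x, ...) {
  cat(sprintf("<complex_catalog> %d complexes (member counts %d-%d)\n",
              length(x), min(lengths(x)), max(lengths(x))))
  invisible(x)
}

#' Gene x tissue expression matrix
#'
#' @param values Numeric matrix (genes in rows, tissues in columns) with
#'   non-negative entries; `rownames` are gene symbols and `colnames` tissue
#'   names.
#' @return An object of class `expression_matrix` (a numeric matrix).  Genes
#'   whose row is entirely zero are tolerated but flagged in the
#'   `degenerate_genes` attribute.
#' @export
expression_matrix <- function(values) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs gene rownames and tissue colnames", call. = FALSE)
  }
  bad <- which(values < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("negative expression value for gene %s in tissue %s",
                 rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]]),
         call. = FALSE)
  }
  degenerate <- rownames(values)[rowSums(values) == 0]
  structure(values, degenerate_genes = degenerate,
            class = c("expression_matrix", "matrix", "array"))
}

#' Read a directed network from a two-column TSV edge list
#'
#' Lines starting with `#` are comments.  A first data line whose first two
#' fields are `regulator`/`target` (case-insensitive) is treated as a header
#' and skipped.  Duplicate edge lines collapse to a single edge (a regulation
#' relation is binary); the number collapsed is reported as a message.
#'
#' @param path Path to the TSV file (regulator TAB target, UTF-8).
#' @param name Network identifier; defaults to the file name without
#'   extension.
#' @return A [tf_network()].
#' @export
read_tf_network <- function(path, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & trimws(lines) != ""
  idx <- which(keep)
  if (length(idx) == 0) stop("empty network in ", path, call. = FALSE)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  short <- lengths(fields) < 2
  if (any(short)) {
    stop(sprintf("parse error in %s: line %d has fewer than 2 tab-separated fields",
                 path, idx[which(short)[1]]), call. = FALSE)
  }
  reg <- trimws(vapply(fields, `[[`, character(1), 1))
  tar <- trimws(vapply(fields, `[[`, character(1), 2))
  if (length(reg) >= 1 &&
      tolower(reg[1]) == "regulator" && tolower(tar[1]) == "target") {
    reg <- reg[-1]
    tar <- tar[-1]
  }
  if (length(reg) == 0) stop("empty network in ", path, call. = FALSE)
  n_dup <- sum(duplicated(paste(reg, tar, sep = "\t")))
  if (n_dup > 0) message(sprintf("%s: collapsed %d duplicate edge line(s)", path, n_dup))
  tf_network(data.frame(regulator = reg, target = tar), name = name)
}

#' Write a network as a two-column TSV edge list
#'
#' @param net A [tf_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tf_network <- function(net, path) {
  stopifnot_network(net)
  readr::write_tsv(net$edges, path, col_names = TRUE)
  invisible(path)
}

#' Read a network collection from a manifest
#'
#' The manifest is a three-column TSV with header `name`, `class_label`,
#' `path`; member paths are resolved relative to the manifest's directory
#' unless absolute.
#'
#' @param manifest_path Path to the manifest TSV.
#' @return A [tf_collection()] preserving manifest order.
#' @export
read_tf_collection <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop("manifest not found: ", manifest_path, call. = FALSE)
  }
  man <- readr::read_tsv(manifest_path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- c("name", "class_label", "path")
  if (!all(required %in% names(man))) {
    stop("manifest must have columns name, class_label, path", call. = FALSE)
  }
  if (nrow(man) == 0) stop("empty manifest: ", manifest_path, call. = FALSE)
  if (anyDuplicated(man$name)) {
    stop("duplicate network name in manifest: ",
         paste(unique(man$name[duplicated(man$name)]), collapse = ", "),
         call. = FALSE)
  }
  base <- dirname(manifest_path)
  paths <- ifelse(grepl("^(/|[A-Za-z]:)", man$path), man$path,
                  file.path(base, man$path))
  nets <- purrr::map2(paths, man$name, read_tf_network)
  tf_collection(nets, man$class_label)
}

#' Write a collection as per-network TSVs plus a manifest
#'
#' @param collection A [tf_collection()].
#' @param dir Output directory (created if missing).
#' @param manifest File name for the manifest inside `dir`.
#' @return The manifest path, invisibly.
#' @export
write_tf_collection <- function(collection, dir, manifest = "manifest.tsv") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rel <- paste0(gsub("[^A-Za-z0-9._-]", "_", names(collection$networks)), ".tsv")
  purrr::walk2(collection$networks, rel,
               function(net, f) write_tf_network(net, file.path(dir, f)))
  man <- dplyr::mutate(collection$classes, path = rel)
  manifest_path <- file.path(dir, manifest)
  readr::write_tsv(man, manifest_path)
  invisible(manifest_path)
}

#' Read a gene set (one symbol per line)
#'
#' @param path Path to the file; blank lines and `#` comments are skipped.
#' @param name Set identifier; defaults to the file name without extension.
#' @return A [gene_set()]; an empty file is an error.
#' @export
read_gene_set <- function(path, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  if (length(lines) == 0) stop("empty gene set in ", path, call. = FALSE)
  gene_set(lines, name = name)
}

#' @rdname read_gene_set
#' @param x A [gene_set()].
#' @export
write_gene_set <- function(x, path) {
  writeLines(gs_members(x), path)
  invisible(path)
}

#' Read a protein-complex catalog
#'
#' Format: TSV with two columns, complex id TAB semicolon-joined member
#' symbols; `#` comments are skipped.
#'
#' @param path Path to the TSV file.
#' @return A [complex_catalog()].
#' @export
read_complex_catalog <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- which(!grepl("^\\s*#", lines) & trimws(lines) != "")
  if (length(keep) == 0) stop("empty complex catalog in ", path, call. = FALSE)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  short <- lengths(fields) < 2
  if (any(short)) {
    stop(sprintf("parse error in %s: line %d has fewer than 2 fields",
                 path, keep[which(short)[1]]), call. = FALSE)
  }
  ids <- trimws(vapply(fields, `[[`, character(1), 1))
  if (length(ids) >= 1 && tolower(ids[1]) == "complex_id") {
    fields <- fields[-1]
    ids <- ids[-1]
  }
  members <- lapply(fields, function(f) strsplit(trimws(f[[2]]), ";", fixed = TRUE)[[1]])
  names(members) <- ids
  complex_catalog(members)
}

#' @rdname read_complex_catalog
#' @param catalog A [complex_catalog()].
#' @export
write_complex_catalog <- function(catalog, path) {
  lines <- c("complex_id\tmembers",
             vapply(seq_along(catalog), function(i) {
               paste0(names(catalog)[i], "\t", paste(catalog[[i]], collapse = ";"))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene x tissue expression matrix
#'
#' Format: TSV with a header row of tissue names; first column holds gene
#' symbols.
#'
#' @param path Path to the TSV file.
#' @return An [expression_matrix()]; negative values are an error naming the
#'   gene and tissue.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (ncol(tab) < 2) stop("expression matrix needs >= 1 tissue column", call. = FALSE)
  genes <- as.character(tab[[1]])
  vals <- as.matrix(tab[, -1, drop = FALSE])
  rownames(vals) <- genes
  expression_matrix(vals)
}

#' @rdname read_expression_matrix
#' @param expr An [expression_matrix()].
#' @export
write_expression_matrix <- function(expr, path) {
  tab <- tibble::as_tibble(unclass(expr), .name_repair = "minimal")
  tab <- dplyr::bind_cols(tibble::tibble(gene = rownames(expr)), tab)
  readr::write_tsv(tab, path)
  invisible(path)
}
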