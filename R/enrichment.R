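#' Hub TFs of a network
#'
#' Ranks nodes by out-degree (regulatory hubs) or total degree and returns
#' the top `fraction`, including all nodes tied with the node at the cutoff
#' rank.  A self-loop counts once toward out-degree and once toward
#' in-degree (so twice toward total degree).
#'
#' @param net A [tf_network()].
#' @param fraction Fraction of nodes to take (default 0.2, the conventional
#'   top-20% cut).
#' @param degree_mode `"out"` or `"total"`.
#' @return A [gene_set()] of hub TFs (attribute `degrees` holds the full
#'   ranked degree table).
#' @export
hubs <- function(net, fraction = 0.2, degree_mode = c("out", "total")) {
  stopifnot_network(net)
  degree_mode <- match.arg(degree_mode)
  if (fraction <= 0 || fraction > 1) stop("`fraction` must be in (0, 1]", call. = FALSE)
  outd <- table(factor(net$edges$regulator, levels = net$nodes))
  ind <- table(factor(net$edges$target, levels = net$nodes))
  deg <- if (degree_mode == "out") as.integer(outd) else as.integer(outd) + as.integer(ind)
  names(deg) <- net$nodes
  ord <- order(-deg, names(deg))
  cutoff_rank <- ceiling(fraction * length(deg))
  threshold <- deg[ord][cutoff_rank]
  members <- names(deg)[deg >= threshold]
  out <- gene_set(sort(members), name = paste0(net$name, "_hubs"))
  attr(out, "degrees") <- tibble::tibble(node = names(deg)[ord],
                                         degree = unname(deg[ord]))
  attr(out, "threshold") <- unname(threshold)
  out
}

#' Hypergeometric enrichment / depletion test
#'
#' With a universe of `N` items of which `K` belong to the class, and a
#' sample of `n` items containing `x` class members: enrichment tests
#' `P[X >= x]`, depletion `P[X <= x]`, for `X ~ Hypergeometric(N, K, n)`.
#' The class is intersected with the universe before testing; the sample
#' must be a subset of the universe.
#'
#' @param universe,class_set,sample [gene_set()]s or character vectors.
#' @param direction `"enrichment"` or `"depletion"`.
#' @return A one-row tibble with columns `N`, `K`, `n`, `x`, `direction`,
#'   `p_value`.
#' @export
hypergeom_test <- function(universe, class_set, sample,
                           direction = c("enrichment", "depletion")) {
  direction <- match.arg(direction)
  u <- unique(gs_members(universe))
  s <- unique(gs_members(sample))
  k <- intersect(unique(gs_members(class_set)), u)
  if (!all(s %in% u)) {
    stop("sample is not a subset of the universe", call. = FALSE)
  }
  N <- length(u)
  K <- length(k)
  n <- length(s)
  x <- length(intersect(s, k))
  p <- if (direction == "enrichment") {
    stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
  } else {
    stats::phyper(x, K, N - K, n, lower.tail = TRUE)
  }
  tibble::tibble(N = N, K = K, n = n, x = x, direction = direction, p_value = p)
}

#' Layer enrichment table across a collection
#'
#' For every network, hierarchy layer (top/core/bottom) and TF class (the
#' network's hubs plus each supplied gene set) this computes both the
#' enrichment and depletion hypergeometric p-values; the universe is the
#' network's own TF set.  The `call` column marks `+` (enriched) or `-`
#' (depleted) when the smaller tail is significant at `alpha`, else `""`.
#'
#' @param collection A [tf_collection()].
#' @param decompositions Named list of [vertex_sort()] results, one per
#'   network (computed if omitted).
#' @param gene_sets List of [gene_set()]s (e.g. essential TFs, HK TFs).
#' @param hub_fraction,hub_mode Passed to [hubs()].
#' @param alpha Significance level for the +/- call (default 0.05).
#' @param bh Add a Benjamini-Hochberg adjusted column over each tail.
#' @return A tibble with columns `network`, `layer`, `class`, `N`, `K`,
#'   `n`, `x`, `p_enrich`, `p_deplete`, `call` (and `q_enrich`, `q_deplete`
#'   when `bh = TRUE`).
#' @export
layer_enrichment_table <- function(collection, decompositions = NULL,
                                   gene_sets = list(), hub_fraction = 0.2,
                                   hub_mode = "out", alpha = 0.05, bh = FALSE) {
  if (is.null(decompositions)) {
    decompositions <- lapply(collection$networks, vertex_sort)
  }
  rows <- purrr::map_dfr(names(collection$networks), function(nm) {
    net <- collection$networks[[nm]]
    decomp <- decompositions[[nm]]
    universe <- net$nodes
    classes <- c(
      list(hubs = gs_members(hubs(net, hub_fraction, hub_mode))),
      stats::setNames(lapply(gene_sets, gs_members),
                      vapply(gene_sets, function(g) attr(g, "name"), character(1)))
    )
    purrr::map_dfr(c("top", "core", "bottom"), function(lay) {
      members <- decomp$node[decomp$layer == lay]
      purrr::map_dfr(names(classes), function(cl) {
        en <- hypergeom_test(universe, classes[[cl]], members, "enrichment")
        de <- hypergeom_test(universe, classes[[cl]], members, "depletion")
        tibble::tibble(network = nm, layer = lay, class = cl,
                       N = en$N, K = en$K, n = en$n, x = en$x,
                       p_enrich = en$p_value, p_deplete = de$p_value)
      })
    })
  })
  rows <- dplyr::mutate(
    rows,
    call = dplyr::case_when(
      .data$p_enrich <= alpha & .data$p_enrich <= .data$p_deplete ~ "+",
      .data$p_deplete <= alpha & .data$p_deplete < .data$p_enrich ~ "-",
      TRUE ~ ""
    )
  )
  if (bh) {
    rows <- dplyr::mutate(rows,
                          q_enrich = stats::p.adjust(.data$p_enrich, "BH"),
                          q_deplete = stats::p.adjust(.data$p_deplete, "BH"))
  }
  rows
}

#' Tissue-expression relative entropy of one gene
#'
#' For expression levels `e_j` over `T` tissues with `f_j = e_j / sum(e)`,
#' the relative entropy is `log2(T) + sum_j f_j log2(f_j)` (with
#' `0 * log2(0) = 0`).  It is 0 when expression is identical in all tissues
#' and `log2(T)` when all expression falls in a single tissue.
#'
#' @param e Non-negative numeric vector of expression levels (one gene row).
#' @return A value in `[0, log2(length(e))]`, in bits.
#' @export
expression_entropy <- function(e) {
  e <- as.numeric(e)
  if (any(is.na(e)) || any(e < 0)) stop("expression levels must be non-negative", call. = FALSE)
  s <- sum(e)
  if (s == 0) stop("all-zero expression row", call. = FALSE)
  f <- e / s
  pos <- f > 0
  # sum f * log2(f * T) == log2(T) + sum f * log2(f), but is exactly 0 for
  # a uniform row and exactly log2(T) for a one-hot row
  sum(f[pos] * log2(f[pos] * length(e)))
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Ranks use midranks for ties.  When `length(a) + length(b) <= 12` and
#' there are no ties the p-value is exact (full null enumeration of the
#' rank-sum distribution); otherwise a normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param a,b Numeric samples (non-empty).
#' @param alternative `"two.sided"`, `"less"` (a tends smaller than b) or
#'   `"greater"`.
#' @return A one-row tibble with columns `statistic` (the Mann-Whitney U of
#'   sample `a`), `p_value`, `method` (`"exact"` or `"normal"`).
#' @export
wilcoxon_rank_sum <- function(a, b, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0) stop("empty sample", call. = FALSE)
  n <- length(a)
  m <- length(b)
  r <- rank(c(a, b))
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- table(r)
  has_ties <- any(ties > 1)
  if (!has_ties && n + m <= 12) {
    p <- switch(alternative,
      less = stats::pwilcox(u, n, m),
      greater = stats::pwilcox(u - 1, n, m, lower.tail = FALSE),
      two.sided = {
        if (u > n * m / 2) {
          min(1, 2 * stats::pwilcox(u - 1, n, m, lower.tail = FALSE))
        } else {
          min(1, 2 * stats::pwilcox(u, n, m))
        }
      })
    method <- "exact"
  } else {
    mu <- n * m / 2
    tie_term <- sum(ties^3 - ties) / ((n + m) * (n + m - 1))
    sigma2 <- n * m / 12 * ((n + m + 1) - tie_term)
    sigma <- sqrt(sigma2)
    if (sigma == 0) {
      p <- 1
    } else {
      z <- u - mu
      correction <- switch(alternative,
        two.sided = sign(z) * 0.5, less = -0.5, greater = 0.5)
      z <- (z - correction) / sigma
      p <- switch(alternative,
        less = stats::pnorm(z),
        greater = stats::pnorm(z, lower.tail = FALSE),
        two.sided = min(1, 2 * min(stats::pnorm(z),
                                   stats::pnorm(z, lower.tail = FALSE))))
    }
    method <- "normal"
  }
  tibble::tibble(statistic = u, p_value = p, method = method)
}

#' Compare expression stability of two TF groups
#'
#' Computes the per-gene tissue-expression relative entropy and tests, by a
#' one-sided Wilcoxon rank-sum test, whether genes in `hk_tfs` (e.g. TFs
#' involved in housekeeping interactions) have *smaller* entropy — i.e. are
#' more stably expressed — than the remaining genes.
#'
#' @param expr An [expression_matrix()].
#' @param hk_tfs A [gene_set()] / character vector; must intersect the
#'   matrix's genes.
#' @return An object of class `entropy_comparison`: list with `table`
#'   (tibble `gene`, `entropy`, `group`) and `p_value`.
#' @export
entropy_comparison <- function(expr, hk_tfs) {
  genes <- rownames(expr)
  members <- gs_members(hk_tfs)
  if (!any(members %in% genes)) {
    stop("`hk_tfs` does not intersect the expression genes", call. = FALSE)
  }
  usable <- genes[rowSums(unclass(expr)) > 0]
  ent <- apply(unclass(expr)[usable, , drop = FALSE], 1, expression_entropy)
  tab <- tibble::tibble(
    gene = usable,
    entropy = unname(ent),
    group = ifelse(usable %in% members, "hk", "other")
  )
  test <- wilcoxon_rank_sum(tab$entropy[tab$group == "hk"],
                            tab$entropy[tab$group == "other"],
                            alternative = "less")
  structure(list(table = tab, p_value = test$p_value, method = test$method),
            class = "entropy_comparison")
}

#' @export
print.entropy_comparison <- function(x, ...) {
  cat(sprintf(
    "<entropy_comparison> %d hk vs %d other genes; one-sided Wilcoxon p = %.3g\n",
    sum(x$table$group == "hk"), sum(x$table$group == "other"), x$p_value
  ))
  invisible(x)
}

#' @export
tidy.entropy_comparison <- function(x, ...) x$table

#' @export
glance.entropy_comparison <- function(x, ...) {
  tibble::tibble(
    n_hk = sum(x$table$group == "hk"),
    n_other = sum(x$table$group == "other"),
    median_hk = stats::median(x$table$entropy[x$table$group == "hk"]),
    median_other = stats::median(x$table$entropy[x$table$group == "other"]),
    p_value = x$p_value,
    method = x$method
  )
}

#' @export
autoplot.entropy_comparison <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$group, y = .data$entropy,
                               fill = .data$group)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "relative entropy (bits)") +
    ggplot2::theme_minimal()
}

#' Empirical one-tailed rank test of one network's statistic
#'
#' Ranks one network's value among the values of all networks in the
#' collection and reports the empirical one-tailed probability of a value
#' at least as extreme, `(r + 1) / (n + 1)` with `r` the number of other
#' networks at least as extreme.  Used e.g. to ask whether one cell type's
#' top-layer fraction is unusually small.
#'
#' @param values Named numeric vector (one value per network).
#' @param network Name of the focal network.
#' @param tail `"low"` (is the value unusually small?) or `"high"`.
#' @return A one-row tibble with `network`, `value`, `tail`, `p_empirical`.
#' @export
empirical_rank_test <- function(values, network, tail = c("low", "high")) {
  tail <- match.arg(tail)
  if (!network %in% names(values)) stop("unknown network: ", network, call. = FALSE)
  v <- values[[network]]
  others <- values[setdiff(names(values), network)]
  r <- if (tail == "low") sum(others <= v) else sum(others >= v)
  tibble::tibble(network = network, value = v, tail = tail,
                 p_empirical = (r + 1) / (length(others) + 1))
}
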