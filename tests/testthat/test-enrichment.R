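# network with prescribed out-degrees: node i regulates the first deg[i]
# partners from a pool of sinks
net_with_outdegrees <- function(deg) {
  regs <- sprintf("R%02d", seq_along(deg))
  sinks <- sprintf("S%02d", seq_len(max(deg)))
  ed <- do.call(rbind, lapply(seq_along(deg), function(i) {
    if (deg[i] == 0) return(NULL)
    data.frame(r = regs[i], t = sinks[seq_len(deg[i])])
  }))
  tf_network(ed, "deg", nodes = c(regs, sinks))
}

test_that("hub selection ranks by degree with tie inclusion and is monotone in fraction", {
  net <- net_with_outdegrees(0:9)  # 10 regulators, distinct out-degrees
  h <- hubs(net, 0.2)
  # 19 nodes total -> rank ceiling(0.2*19) = 4 -> top 4 out-degrees 9,8,7,6
  expect_setequal(unclass(h), c("R10", "R09", "R08", "R07"))
  expect_setequal(unclass(hubs(net, 1)), net$nodes)

  tie <- net_with_outdegrees(c(5, 5, 5, 1, 1))
  ht <- hubs(tie, 0.2)  # 10 nodes, rank 2 -> threshold 5 -> all three tied
  expect_setequal(unclass(ht), c("R01", "R02", "R03"))

  for (f in c(0.1, 0.3, 0.5, 0.8)) {
    expect_true(all(unclass(hubs(net, f)) %in% unclass(hubs(net, f + 0.2))))
  }

  # total-degree mode counts self-loops twice
  loopy <- tf_network(data.frame(r = c("A", "A", "B"), t = c("A", "B", "C")), "l")
  deg_tab <- attr(hubs(loopy, 1, "total"), "degrees")
  expect_equal(deg_tab$degree[deg_tab$node == "A"], 3)
})

test_that("hypergeometric tails match exhaustive enumeration", {
  expect_equal(hypergeom_test(letters[1:5], letters[1:2], letters[1:2],
                              "enrichment")$p_value, 0.1)
  expect_equal(hypergeom_test(letters[1:5], letters[1:2], letters[4:5],
                              "depletion")$p_value, 0.3)
  expect_equal(hypergeom_test(letters[1:5], letters[1:5], letters[1:3],
                              "enrichment")$p_value, 1)
  expect_error(hypergeom_test(letters[1:4], letters[1:2], letters[4:6]),
               "subset")

  set.seed(21)
  for (i in 1:25) {
    N <- sample(5:12, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    universe <- sprintf("g%02d", 1:N)
    smp <- sample(universe, n)
    x <- sum(smp %in% universe[1:K])
    for (dir in c("enrichment", "depletion")) {
      got <- hypergeom_test(universe, universe[1:K], smp, dir)$p_value
      expect_equal(got, hyper_oracle(N, K, n, x, dir), tolerance = 1e-12)
    }
    # tail identity: P[X >= x] + P[X <= x] = 1 + P[X = x]
    pe <- hypergeom_test(universe, universe[1:K], smp, "enrichment")$p_value
    pd <- hypergeom_test(universe, universe[1:K], smp, "depletion")$p_value
    expect_equal(pe + pd, 1 + stats::dhyper(x, K, N - K, n), tolerance = 1e-12)
  }
})

test_that("layer enrichment calls a planted core-concentrated class correctly", {
  # 4 top, 12-cycle core, 4 bottom; the class is exactly the core
  core <- sprintf("c%02d", 1:12)
  ed <- rbind(
    data.frame(r = core, t = c(core[-1], core[1])),
    data.frame(r = sprintf("t%d", 1:4), t = core[1:4]),
    data.frame(r = core[5:8], t = sprintf("b%d", 1:4))
  )
  net <- tf_network(ed, "planted")
  col <- tf_collection(list(net), "x")
  tab <- layer_enrichment_table(col, gene_sets = list(gene_set(core, "core_class")))
  cls <- tab[tab$class == "core_class", ]
  expect_equal(cls$call[cls$layer == "core"], "+")
  expect_equal(cls$call[cls$layer == "top"], "-")
  expect_equal(cls$call[cls$layer == "bottom"], "-")

  # a class disjoint from the network gives x = 0 everywhere
  tab2 <- layer_enrichment_table(col, gene_sets = list(gene_set("ZZZ", "absent")))
  expect_true(all(tab2$x[tab2$class == "absent"] == 0))

  # row count = networks x layers x classes
  expect_equal(nrow(tab), 1 * 3 * 2)
})

test_that("expression entropy obeys the closed forms, bounds and scale invariance", {
  expect_equal(expression_entropy(rep(7, 79)), 0)
  expect_equal(expression_entropy(c(10, 0, 0, 0, 0, 0, 0, 0)), 3)  # log2(8)
  expect_equal(expression_entropy(c(1, 1, 0, 0)), 1)
  expect_error(expression_entropy(c(0, 0)), "all-zero")
  expect_error(expression_entropy(c(1, -1)), "non-negative")

  set.seed(22)
  for (i in 1:20) {
    e <- stats::rgamma(sample(3:20, 1), 1)
    h <- expression_entropy(e)
    expect_gte(h, 0)
    expect_lte(h, log2(length(e)) + 1e-12)
    expect_equal(expression_entropy(e * 3.7), h, tolerance = 1e-12)
  }
})

test_that("Wilcoxon rank-sum p-values match full split enumeration", {
  expect_equal(wilcoxon_rank_sum(1:3, 10:12, "less")$p_value, 0.05)
  same <- wilcoxon_rank_sum(c(1, 2, 2, 3), c(3, 1, 2, 2))
  expect_gte(same$p_value, 0.99)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "empty")

  set.seed(23)
  for (i in 1:20) {
    n <- sample(2:5, 1)
    m <- sample(2:5, 1)
    a <- stats::rnorm(n)
    b <- stats::rnorm(m)
    for (alt in c("two.sided", "less", "greater")) {
      got <- wilcoxon_rank_sum(a, b, alt)
      expect_equal(got$method, "exact")
      expect_equal(got$p_value, wilcox_oracle(a, b, alt), tolerance = 1e-12)
    }
  }

  # with ties the normal approximation is used and stays close to
  # wilcox.test's tie-corrected approximation
  a <- c(1, 2, 2, 3, 5, 5, 6, 8)
  b <- c(2, 4, 4, 5, 7, 7, 8, 9)
  got <- wilcoxon_rank_sum(a, b, "less")
  expect_equal(got$method, "normal")
  ref <- stats::wilcox.test(a, b, alternative = "less", exact = FALSE,
                            correct = TRUE)$p.value
  expect_equal(got$p_value, ref, tolerance = 1e-10)
})

test_that("entropy comparison separates planted stable genes from variable ones", {
  ge <- generate_expression(n_genes = 60, n_tissues = 20, stable_fraction = 0.5,
                            noise_sd = 0.05, concentration = 0.05, seed = 3)
  stable <- ge$truth$gene[ge$truth$group == "stable"]
  cmp <- entropy_comparison(ge$expr, stable)
  expect_lt(cmp$p_value, 0.01)
  expect_true(all(cmp$table$entropy >= 0))

  # all-constant matrix: all entropies zero, no separation
  flat <- expression_matrix(matrix(5, 10, 4,
                                   dimnames = list(sprintf("g%d", 1:10),
                                                   sprintf("t%d", 1:4))))
  cmp2 <- entropy_comparison(flat, sprintf("g%d", 1:5))
  expect_true(all(cmp2$table$entropy == 0))
  expect_gte(cmp2$p_value, 0.99)
  expect_error(entropy_comparison(flat, "nope"), "intersect")
})

test_that("the empirical rank test flags an outlying network", {
  vals <- c(a = 0.20, b = 0.22, c = 0.25, d = 0.24, e = 0.06)
  out <- empirical_rank_test(vals, "e", "low")
  expect_equal(out$p_empirical, 1 / 5)
  expect_equal(empirical_rank_test(vals, "c", "high")$p_empirical, 1 / 5)
})
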