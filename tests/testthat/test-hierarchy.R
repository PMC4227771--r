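chain <- tf_network(data.frame(r = c("a", "b"), t = c("b", "c")), "chain")
cycle3 <- tf_network(data.frame(r = c("a", "b", "c"), t = c("b", "c", "a")), "cycle")
mixed <- tf_network(
  data.frame(r = c("e", "a", "b", "c", "c"), t = c("a", "b", "c", "a", "d")),
  "mixed"
)

test_that("SCCs match the mutual-reachability oracle on random digraphs", {
  expect_equal(unique(scc_membership(cycle3)$scc_id), 1L)
  expect_equal(scc_membership(chain)$scc_id, 1:3)
  set.seed(101)
  for (i in 1:60) {
    net <- rand_digraph(sample(2:10, 1), stats::runif(1, 0.1, 0.5),
                        self_loops = (i %% 3 == 0))
    got <- scc_membership(net)
    want <- scc_oracle(net)
    expect_equal(got$scc_id, unname(want[got$node]))
  }
})

test_that("vertex sort reproduces the forced small-case layers and level spans", {
  d <- vertex_sort(chain)
  expect_equal(as.character(d$layer), c("top", "core", "bottom"))
  expect_equal(d$level_low, 3:1)
  expect_equal(d$level_high, 3:1)
  expect_equal(attr(d, "height"), 3L)

  d2 <- vertex_sort(mixed)
  lay <- setNames(as.character(d2$layer), d2$node)
  expect_equal(unname(lay[c("a", "b", "c")]), rep("core", 3))
  expect_equal(unname(lay["e"]), "top")
  expect_equal(unname(lay["d"]), "bottom")
})

test_that("vertex sort agrees with the reachability-condensation oracle", {
  set.seed(202)
  for (i in 1:60) {
    net <- rand_digraph(sample(2:10, 1), stats::runif(1, 0.1, 0.5),
                        self_loops = (i %% 4 == 0))
    got <- as.data.frame(vertex_sort(net))
    want <- vertex_sort_oracle(net)
    expect_equal(as.character(got$layer), want$layer)
    expect_equal(got$scc_id, want$scc_id)
    expect_equal(got$level_low, want$level_low)
    expect_equal(got$level_high, want$level_high)
  }
})

test_that("layer assignment is invariant to relabeling and self-loops", {
  set.seed(33)
  net <- rand_digraph(8, 0.3)
  d <- vertex_sort(net)
  lay <- setNames(as.character(d$layer), d$node)

  # relabel nodes with a random permutation of fresh names
  perm <- setNames(sprintf("Z%02d", sample(seq_along(net$nodes))), net$nodes)
  ed <- data.frame(regulator = unname(perm[net$edges$regulator]),
                   target = unname(perm[net$edges$target]))
  net2 <- tf_network(ed, "relabeled", nodes = unname(perm))
  d2 <- vertex_sort(net2)
  lay2 <- setNames(as.character(d2$layer), d2$node)
  expect_equal(unname(lay2[unname(perm[names(lay)])]), unname(lay))

  # adding self-loops changes nothing
  with_loops <- tf_network(rbind(net$edges,
                                 data.frame(regulator = net$nodes, target = net$nodes)),
                           "loops", nodes = net$nodes)
  d3 <- vertex_sort(with_loops)
  expect_equal(as.character(d3$layer), as.character(d$layer))
  expect_equal(d3$level_low, d$level_low)
})

test_that("level spans are monotone along condensation edges", {
  set.seed(44)
  for (i in 1:20) {
    net <- rand_digraph(sample(4:10, 1), 0.3)
    d <- vertex_sort(net)
    low <- setNames(d$level_low, d$node)
    scc <- setNames(d$scc_id, d$node)
    ed <- net$edges[net$edges$regulator != net$edges$target, ]
    cross <- ed[scc[ed$regulator] != scc[ed$target], ]
    if (nrow(cross) > 0) {
      expect_true(all(low[cross$regulator] >= low[cross$target] + 1L))
    }
    expect_true(all(d$level_low >= 1 & d$level_low <= d$level_high &
                      d$level_high <= attr(d, "height")))
  }
})

test_that("layer proportions sum correctly and handle isolated nodes", {
  pr <- layer_proportions(vertex_sort(chain))
  expect_equal(pr$fraction[pr$layer != "isolated"], rep(1 / 3, 3))
  pr2 <- layer_proportions(vertex_sort(cycle3))
  expect_equal(pr2$fraction[pr2$layer == "core"], 1)

  iso <- tf_network(data.frame(r = c("a", "x"), t = c("b", "x")), "iso")
  d <- vertex_sort(iso)
  expect_equal(as.character(d$layer[d$node == "x"]), "isolated")
  pr3 <- layer_proportions(d)
  expect_equal(sum(pr3$fraction[pr3$layer %in% c("top", "core", "bottom")]), 1)
  expect_equal(pr3$fraction[pr3$layer == "isolated"], 1 / 3)
})

test_that("every non-self link lands in exactly one layer-pair category", {
  ld <- link_distribution(mixed, vertex_sort(mixed))
  expect_equal(ld$fraction[ld$category == "within_core"], 3 / 5)
  expect_equal(ld$fraction[ld$category == "top_core"], 1 / 5)
  expect_equal(ld$fraction[ld$category == "core_bottom"], 1 / 5)
  expect_equal(sum(ld$fraction), 1)

  # sources -> sinks only: no within-core links
  bip <- tf_network(data.frame(r = c("s1", "s1", "s2"), t = c("t1", "t2", "t2")), "bip")
  ldb <- link_distribution(bip, vertex_sort(bip))
  expect_equal(ldb$fraction[ldb$category == "within_core"], 0)
  expect_equal(ldb$fraction[ldb$category == "top_bottom"], 1)

  set.seed(55)
  for (i in 1:15) {
    net <- rand_digraph(sample(3:9, 1), 0.3, self_loops = TRUE)
    ld <- link_distribution(net, vertex_sort(net))
    non_self <- sum(net$edges$regulator != net$edges$target)
    expect_equal(sum(ld$n), non_self)
  }
})

test_that("local reaching centrality equals the BFS-closure count", {
  star <- tf_network(data.frame(r = "hub", t = sprintf("leaf%d", 1:9)), "star")
  expect_equal(local_reaching_centrality(star, "hub"), 1.0)
  expect_equal(local_reaching_centrality(chain)$lrc, c(1, 0.5, 0))
  expect_error(local_reaching_centrality(chain, "zz"), "unknown node")

  set.seed(66)
  for (i in 1:25) {
    net <- rand_digraph(sample(2:10, 1), 0.3)
    got <- local_reaching_centrality(net)
    want <- rowSums(reach_oracle(net)) / (length(net$nodes) - 1)
    expect_equal(setNames(got$lrc, got$node), want)
  }
})

test_that("global reaching centrality hits its closed-form limits", {
  expect_equal(global_reaching_centrality(chain), 0.75)
  star <- tf_network(data.frame(r = "h", t = sprintf("l%d", 1:7)), "star")
  expect_equal(global_reaching_centrality(star), 1.0)
  full <- expand.grid(r = letters[1:5], t = letters[1:5], stringsAsFactors = FALSE)
  complete <- tf_network(full[full$r != full$t, ], "complete")
  expect_equal(global_reaching_centrality(complete), 0.0)
})

test_that("LRC layer-ordering violations are found and characterised exactly", {
  expect_equal(nrow(lrc_layer_ordering_check(chain, vertex_sort(chain))), 0)

  # a degenerate top node regulating a single sink, next to a rich core
  weak <- tf_network(data.frame(
    r = c("t1", "a", "b", "c", "c"),
    t = c("x", "b", "c", "a", "d")
  ), "weak_top")
  d <- vertex_sort(weak)
  viol <- lrc_layer_ordering_check(weak, d)
  expect_true(all(viol$upper == "t1"))
  expect_setequal(viol$lower, c("a", "b", "c"))
  # direct LRC computation confirms each reported pair
  lrc <- setNames(local_reaching_centrality(weak)$lrc,
                  local_reaching_centrality(weak)$node)
  expect_true(all(lrc[viol$upper] <= lrc[viol$lower]))

  # empty violation list <=> min over upper layer > max over lower layer
  set.seed(77)
  for (i in 1:15) {
    net <- rand_digraph(sample(4:9, 1), 0.35)
    d <- vertex_sort(net)
    v <- lrc_layer_ordering_check(net, d)
    lrc <- setNames(local_reaching_centrality(net)$lrc, net$nodes)
    lay <- setNames(as.character(d$layer), d$node)
    ord_ok <- function(up, lo) {
      u <- lrc[names(lay)[lay == up]]
      l <- lrc[names(lay)[lay == lo]]
      length(u) == 0 || length(l) == 0 || min(u) > max(l)
    }
    expect_equal(nrow(v) == 0, ord_ok("top", "core") && ord_ok("core", "bottom"))
  }
})
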