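test_that("target feature matrix flags exactly the targets of the TF set", {
  col <- tf_collection(list(
    tf_network(data.frame(r = "S", t = "X"), "c1"),
    tf_network(data.frame(r = c("S", "X"), t = c("Y", "S")), "c2")
  ), c("a", "b"))
  fm <- target_feature_matrix(col, gene_set("S"))
  expect_equal(colnames(fm), c("S", "X", "Y"))
  expect_equal(unclass(fm)["c1", ], c(S = 0, X = 1, Y = 0))
  expect_equal(unclass(fm)["c2", ], c(S = 0, X = 0, Y = 1))
  expect_error(target_feature_matrix(col, gene_set("ZZ")), "disjoint")

  # identical networks give identical rows; random collections match a
  # direct edge-scan oracle
  set.seed(12)
  nets <- lapply(1:4, function(i) tf_network(rand_digraph(7, 0.3)$edges,
                                             sprintf("n%d", i)))
  col2 <- tf_collection(c(nets, list(tf_network(nets[[1]]$edges, "n1b"))),
                        rep("x", 5))
  A <- sample(union_nodes(col2), 3)
  fm2 <- target_feature_matrix(col2, A)
  expect_equal(unclass(fm2)["n1", ], unclass(fm2)["n1b", ])
  for (nm in rownames(fm2)) {
    net <- col2$networks[[nm]]
    for (tf in colnames(fm2)) {
      hit <- any(net$edges$regulator %in% A & net$edges$target == tf)
      expect_equal(unname(unclass(fm2)[nm, tf]), as.numeric(hit))
    }
  }
})

test_that("NND features are degree shares summing to one per network", {
  col <- tf_collection(list(
    tf_network(data.frame(r = "A", t = "B"), "one"),
    tf_network(data.frame(r = c("A", "B"), t = c("B", "C")), "two")
  ), c("x", "y"))
  fm <- nnd_feature_matrix(col)
  expect_equal(unclass(fm)["one", ], c(A = 0.5, B = 0.5, C = 0))
  expect_equal(unname(rowSums(unclass(fm))), c(1, 1))

  set.seed(13)
  col2 <- tf_collection(lapply(1:3, function(i) {
    tf_network(rand_digraph(6, 0.4, self_loops = TRUE)$edges, sprintf("n%d", i))
  }), rep("x", 3))
  fm2 <- nnd_feature_matrix(col2)
  expect_equal(unname(rowSums(unclass(fm2))), rep(1, 3))
  for (nm in rownames(fm2)) {
    ed <- col2$networks[[nm]]$edges
    for (tf in colnames(fm2)) {
      deg <- sum(ed$regulator == tf) + sum(ed$target == tf)
      expect_equal(unname(unclass(fm2)[nm, tf]), deg / (2 * nrow(ed)))
    }
  }
})

test_that("PCA projection preserves geometry and matches the covariance eigen-oracle", {
  # collinear points: one informative component, distances preserved
  line <- outer(c(0, 1, 3, 6), c(1, 2, 2))
  pr <- pca_project(line, 3)
  ev <- attr(pr, "explained_variance")
  expect_equal(sum(ev > 1e-10), 1)
  expect_equal(as.numeric(dist(pr[, 1, drop = FALSE])), as.numeric(dist(line)))

  # centering invariance
  set.seed(14)
  m <- matrix(rnorm(20), 5, 4)
  shifted <- sweep(m, 2, c(5, -3, 2, 100), `+`)
  expect_equal(pca_project(m, 3), pca_project(shifted, 3))

  # eigen-oracle with the same sign convention
  pr2 <- pca_project(m, 3)
  cm <- scale(m, center = TRUE, scale = FALSE)
  eg <- eigen(stats::cov(cm))
  for (j in 1:3) {
    v <- eg$vectors[, j]
    v <- v * sign(v[which.max(abs(v))])
    expect_equal(unname(pr2[, j]), unname(as.numeric(cm %*% v)), tolerance = 1e-8)
  }
})

test_that("Ward clustering recovers separated clouds and the exhaustive merge order", {
  set.seed(15)
  cloud <- rbind(matrix(rnorm(10, 0, 0.1), 5, 2),
                 matrix(rnorm(10, 10, 0.1), 5, 2))
  rownames(cloud) <- sprintf("p%d", 1:10)
  part <- ward_cluster(cloud, 2)
  expect_equal(length(unique(part$labels$cluster[1:5])), 1)
  expect_equal(length(unique(part$labels$cluster[6:10])), 1)
  expect_false(part$labels$cluster[1] == part$labels$cluster[6])

  expect_equal(ward_cluster(cloud, 10)$labels$cluster, 1:10)
  expect_error(ward_cluster(cloud, 11), "between 1 and")

  # merge heights are non-decreasing and match exhaustive agglomeration
  for (i in 1:10) {
    pts <- matrix(rnorm(10), 5, 2)
    rownames(pts) <- sprintf("q%d", 1:5)
    got <- ward_cluster(pts, 2)
    expect_true(all(diff(got$tree$height) >= -1e-12))
    oracle <- ward_oracle(pts, k = 2)
    expect_equal(got$tree$height, oracle$heights, tolerance = 1e-10)
    expect_equal(ri_oracle(setNames(got$labels$cluster, got$labels$name),
                           setNames(oracle$partition, rownames(pts))), 1)
  }
})

test_that("Rand index agrees with pair enumeration and detects equality", {
  p1 <- c(a = 1, b = 1, c = 2)
  p2 <- c(a = 1, b = 2, c = 3)
  expect_equal(rand_index(p1, p1), 1)
  expect_equal(rand_index(p1, p2), 2 / 3)
  expect_equal(rand_index(p1, p2), rand_index(p2, p1))
  expect_error(rand_index(p1, c(a = 1, d = 2, c = 1)), "different item sets")

  set.seed(16)
  for (i in 1:30) {
    n <- sample(3:8, 1)
    a <- setNames(sample(1:3, n, replace = TRUE), letters[1:n])
    b <- setNames(sample(1:3, n, replace = TRUE), letters[1:n])
    expect_equal(rand_index(a, b), ri_oracle(a, b))
    same_partition <- identical(
      unname(split(names(a), a)[order(sapply(split(names(a), a), min))]),
      unname(split(names(b), b)[order(sapply(split(names(b), b), min))])
    )
    expect_equal(rand_index(a, b) == 1, same_partition)
  }
})

test_that("the classification pipeline recovers planted classes and handles degeneracy", {
  gen <- small_planted()
  col <- gen$collection
  ref <- truth_reference(gen$truth)
  fit <- classify_collection(col, gen$truth$marker_set, k = 4, reference = ref)
  expect_equal(fit$ri, 1.0)
  expect_equal(rand_index(fit$labels[, c("name", "cluster")], fit$labels[, c("name", "cluster")]), 1)

  # pipeline invariant under row reordering of the collection
  perm <- sample(seq_along(col$networks))
  col_perm <- tf_collection(col$networks[perm], col$classes$class_label[perm])
  fit_perm <- classify_collection(col_perm, gen$truth$marker_set, k = 4,
                                  reference = ref)
  expect_equal(fit_perm$ri, fit$ri)

  # identically wired TF set: degenerate features, single cluster
  ed <- data.frame(r = c("S", "A"), t = c("X", "B"))
  col2 <- tf_collection(lapply(1:3, function(i) {
    tf_network(ed, sprintf("c%d", i))
  }), c("g1", "g1", "g2"))
  ref2 <- data.frame(name = c("c1", "c2", "c3"), cluster = c(1, 1, 2))
  expect_warning(fit2 <- classify_collection(col2, "S", reference = ref2),
                 "degenerate")
  expect_equal(fit2$ri,
               ri_oracle(c(c1 = 1, c2 = 1, c3 = 1), c(c1 = 1, c2 = 1, c3 = 2)))
})

test_that("the random TF-set sweep is reproducible and carries planted signal", {
  gen <- small_planted()
  col <- gen$collection
  ref <- truth_reference(gen$truth)
  sw <- random_tf_set_sweep(col, set_size = 5, n_draws = 6, seed = 9,
                            reference = ref)
  expect_identical(
    tibble::as_tibble(sw),
    tibble::as_tibble(random_tf_set_sweep(col, set_size = 5, n_draws = 6,
                                          seed = 9, reference = ref)))

  # each row reduces to classify_collection on that draw
  tfs1 <- strsplit(sw$tfs[1], ";")[[1]]
  fit1 <- suppressWarnings(classify_collection(col, tfs1, reference = ref))
  expect_equal(sw$rand_index[1], fit1$ri)

  # sweep RIs exceed the label-permuted baseline (Wilcoxon, one-sided)
  set.seed(31)
  ref_perm <- ref
  ref_perm$cluster <- sample(ref_perm$cluster)
  sw0 <- random_tf_set_sweep(col, set_size = 5, n_draws = 6, seed = 9,
                             reference = ref_perm)
  p <- wilcoxon_rank_sum(sw0$rand_index, sw$rand_index, "less")$p_value
  expect_lt(p, 0.05)
  expect_error(random_tf_set_sweep(col, set_size = 10000), "exceeds")
})
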