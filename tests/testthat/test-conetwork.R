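test_that("SparCC rejects underdetermined inputs", {
  m <- random_counts(10, 3, seed = 1)
  expect_error(sparcc(m), "at least 4 taxa")
  expect_error(sparcc(random_counts(3, 6, seed = 1)), "at least 4 samples")
})

test_that("SparCC recovers a planted basis correlation", {
  counts <- lognormal_basis_counts(20, 300, seed = 21, rho = 0.9)
  fit <- sparcc(counts, seed = 1)
  expect_equal(fit$r["t1", "t2"], 0.9, tolerance = 0.15)
  # an arbitrary independent pair stays weak
  expect_lt(abs(fit$r["t5", "t9"]), 0.5)
  expect_equal(fit$r, t(fit$r))
  expect_true(all(abs(fit$r) <= 1))
})

test_that("bootstrap p-values follow the add-one exceedance formula", {
  counts <- lognormal_basis_counts(6, 120, seed = 31, rho = 0.95)
  fit <- sparcc(counts, n_inner = 5, seed = 2)
  p <- bootstrap_pvalues(counts, fit, n_boot = 100, seed = 3, n_inner = 5)
  # the planted near-perfect pair is never exceeded under permutation:
  # p = (1 + 0) / (100 + 1)
  expect_equal(p["t1", "t2"], 1 / 101)
  expect_lt(p["t1", "t2"], 0.01)
  expect_true(all(p > 0 & p <= 1))
  expect_equal(p, t(p))
  # k exceedances out of B give (1 + k) / (B + 1): spot the grid
  expect_equal((1 + 5) / (100 + 1), 6 / 101)
})

test_that("bootstrap p-values are super-uniform under the permutation null", {
  hits <- 0
  total <- 0
  for (s in 1:12) {
    counts <- lognormal_basis_counts(8, 40, seed = 100 + s)
    perm <- withr::with_seed(s, apply(counts, 2, sample))
    rownames(perm) <- rownames(counts)
    fit <- sparcc(perm, n_inner = 4, seed = s)
    p <- bootstrap_pvalues(perm, fit, n_boot = 30, seed = s, n_inner = 4)
    up <- p[upper.tri(p)]
    hits <- hits + sum(up <= 0.1)
    total <- total + length(up)
  }
  # P(p <= 0.1) must not exceed 0.1 (within binomial noise)
  expect_lt(hits / total, 0.1 + 3 * sqrt(0.1 * 0.9 / total))
})

test_that("meta-network thresholding keeps only strong significant edges", {
  taxa <- c("a", "b", "c")
  r <- matrix(0, 3, 3, dimnames = list(taxa, taxa)); diag(r) <- 1
  p <- matrix(1, 3, 3, dimnames = list(taxa, taxa))
  r["a", "b"] <- r["b", "a"] <- 0.80; p["a", "b"] <- p["b", "a"] <- 0.005
  r["a", "c"] <- r["c", "a"] <- -0.76; p["a", "c"] <- p["c", "a"] <- 0.005
  r["b", "c"] <- r["c", "b"] <- 0.80; p["b", "c"] <- p["c", "b"] <- 0.02
  meta <- build_metanetwork(r, p)
  expect_equal(nrow(meta$edges), 2)
  ab <- meta$edges[meta$edges$taxon_i == "a" & meta$edges$taxon_j == "b", ]
  expect_equal(ab$sign, "+")
  ac <- meta$edges[meta$edges$taxon_j == "c", ]
  expect_equal(ac$sign, "-")
  expect_equal(glance(meta)$n_edges, 2)

  r_bad <- r; r_bad[1, 2] <- 0.3
  expect_error(build_metanetwork(r_bad, p), "symmetric")
})

test_that("per-sample subnetworks are induced by presence", {
  taxa <- c("a", "b", "c", "d")
  r <- diag(4); dimnames(r) <- list(taxa, taxa)
  p <- matrix(1, 4, 4, dimnames = list(taxa, taxa))
  r["a", "b"] <- r["b", "a"] <- 0.9; p["a", "b"] <- p["b", "a"] <- 0.001
  r["c", "d"] <- r["d", "c"] <- 0.8; p["c", "d"] <- p["d", "c"] <- 0.001
  meta <- build_metanetwork(r, p)

  g_all <- sample_subnetwork(meta, c(a = 1, b = 1, c = 1, d = 1))
  expect_equal(igraph::ecount(g_all), igraph::ecount(meta$graph))

  g_ab <- sample_subnetwork(meta, c(a = 1, b = 2, c = 0, d = 0))
  expect_equal(igraph::vcount(g_ab), 2)
  expect_equal(igraph::ecount(g_ab), 1)

  g_ac <- sample_subnetwork(meta, c(a = 1, b = 0, c = 1, d = 0))
  expect_equal(igraph::ecount(g_ac), 0)
  expect_equal(topology_metrics(g_ac)$connectivity, 0)
})

test_that("topology metrics match hand-computed graphs", {
  tri <- igraph::make_graph(~ A - B, B - C, C - A)
  t1 <- topology_metrics(tri)
  expect_equal(t1$size, 3)
  expect_equal(t1$connectivity, 3)
  expect_equal(t1$mean_degree, 2)
  expect_equal(t1$clustering, 1)

  path <- igraph::make_graph(~ A - B, B - C)
  t2 <- topology_metrics(path)
  expect_equal(t2$mean_degree, 4 / 3)
  expect_equal(t2$clustering, 0)

  two_tri <- igraph::make_graph(~ A - B, B - C, C - A, D - E, E - F, F - D)
  expect_equal(topology_metrics(two_tri)$modularity, 0.5)

  expect_warning(t0 <- topology_metrics(igraph::make_empty_graph(0)), "empty")
  expect_equal(t0$size, 0)
})

test_that("cohesion reproduces the worked example and its invariances", {
  taxa <- c("A", "B", "C")
  r <- diag(3); dimnames(r) <- list(taxa, taxa)
  p <- matrix(1, 3, 3, dimnames = list(taxa, taxa))
  r["A", "B"] <- r["B", "A"] <- 0.8; p["A", "B"] <- p["B", "A"] <- 0.001
  r["A", "C"] <- r["C", "A"] <- -0.8; p["A", "C"] <- p["C", "A"] <- 0.001
  meta <- build_metanetwork(r, p)
  out <- cohesion(meta, c(A = 0.5, B = 0.3, C = 0.2))
  expect_equal(out$pos_cohesion, 0.64)
  expect_equal(out$neg_pos_ratio, 0.875)

  # linear in abundances
  half <- cohesion(meta, c(A = 0.25, B = 0.15, C = 0.1))
  expect_equal(half$pos_cohesion, 0.32)
  expect_equal(half$neg_pos_ratio, 0.875)

  # all-positive network: ratio 0
  r2 <- r; r2["A", "C"] <- r2["C", "A"] <- 0.8
  meta2 <- build_metanetwork(r2, p)
  out2 <- cohesion(meta2, c(A = 0.5, B = 0.3, C = 0.2))
  expect_equal(out2$neg_pos_ratio, 0)

  # connected taxa absent: zero cohesion, undefined ratio
  expect_warning(out3 <- cohesion(meta, c(A = 0, B = 0, C = 0)), "undefined")
  expect_equal(out3$pos_cohesion, 0)
  expect_true(is.na(out3$neg_pos_ratio))
})

test_that("complementarity equals hand path-unions on the toy tree", {
  tree <- toy_tree()
  expect_equal(complementarity(c("A", "B"), tree), 3)
  expect_equal(complementarity(c("A", "C"), tree), 5)
  expect_equal(complementarity(c("A", "B", "C"), tree), 7)
  expect_equal(complementarity("A", tree), 0)
  expect_error(complementarity(c("A", "Z"), tree), "missing from the tree")
})

test_that("complementarity matches the brute-force subtree oracle", {
  tree <- simulate_tree(50, seed = 44)
  for (s in 1:30) {
    k <- withr::with_seed(s, sample(2:20, 1))
    tips <- withr::with_seed(s + 500, sample(tree$tip.label, k))
    expect_equal(complementarity(tips, tree),
                 subtree_length_bruteforce(tree, tips),
                 tolerance = 1e-12)
  }
  expect_equal(complementarity(tree$tip.label, tree),
               sum(tree$edge.length), tolerance = 1e-12)
  # monotone under adding tips
  t1 <- complementarity(tree$tip.label[1:5], tree)
  t2 <- complementarity(tree$tip.label[1:9], tree)
  expect_gte(t2, t1)
})

test_that("only network-participating taxa enter the complementarity proxy", {
  tree <- simulate_tree(6, seed = 3)
  g <- igraph::make_graph(~ ASV0001 - ASV0002)
  g <- igraph::add_vertices(g, 1, name = "ASV0003") # present but unconnected
  with_deg <- complementarity(g, tree)
  expect_equal(with_deg,
               subtree_length_bruteforce(tree, c("ASV0001", "ASV0002")))
  all_nodes <- complementarity(g, tree, connected_only = FALSE)
  expect_equal(all_nodes,
               subtree_length_bruteforce(tree,
                                         c("ASV0001", "ASV0002", "ASV0003")))
})

test_that("independent compositional data yield no spurious strong edges", {
  counts <- lognormal_basis_counts(15, 150, seed = 77)
  fit <- sparcc(counts, seed = 9)
  off <- abs(fit$r[upper.tri(fit$r)])
  expect_lt(max(off), 0.75)
})
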