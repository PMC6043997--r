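test_that("node weights count common neighbors along incident edges", {
  ## triangle: every edge has one common neighbor, every node two incident
  w <- node_weights(graph_triangle())
  expect_equal(unname(w[c("a", "b", "c")]), c(2, 2, 2))

  ## star: no triangles, all weights zero
  star <- as_network(edge_fixture(list(c("h", "x"), c("h", "y"), c("h", "z"))))
  expect_equal(unname(node_weights(star)), rep(0, 4))

  ## two triangles sharing vertex c: the shared vertex has maximal weight
  two <- graph_cliques(c("a", "b", "c"), c("c", "d", "e"))
  w2 <- node_weights(two)
  expect_equal(names(which.max(w2)), "c")
  expect_equal(unname(w2["c"]), 4)
})

test_that("cluster growth respects density and cluster-property thresholds", {
  ## triangle at d_in 0.9: every addition keeps density 1
  cl <- grow_cluster(graph_triangle(), "a", d_in = 0.9, cp_in = 0.5)
  expect_setequal(cl, c("a", "b", "c"))
  expect_equal(attr(cl, "density"), 1)

  ## two triangles joined by a bridge at d_in 0.9: the bridge node would
  ## drop density to 4/6, so growth stops at the seed triangle
  cl2 <- grow_cluster(graph_two_triangles_bridge(), "a", 0.9, 0.5)
  expect_setequal(cl2, c("a", "b", "c"))

  ## isolated-seed growth yields a singleton with density 1
  lone <- as_network(edge_fixture(list(c("a", "b"))))
  lone$nodes <- c(lone$nodes, "z")
  cl3 <- grow_cluster(lone, "z", 0.5)
  expect_equal(as.character(cl3), "z")
  expect_equal(attr(cl3, "density"), 1)
})

test_that("clustering covers every node and recovers disjoint cliques", {
  g <- graph_cliques(sprintf("a%d", 1:8), sprintf("b%d", 1:8))
  cs <- cluster_network(g, d_in = 0.5, cp_in = 0.5)
  expect_length(cs$clusters, 2L)
  expect_setequal(cs$clusters[[1]], sprintf("a%d", 1:8))
  expect_setequal(cs$clusters[[2]], sprintf("b%d", 1:8))
  expect_equal(cs$density, c(1, 1))
  expect_setequal(unlist(cs$clusters), g$nodes)

  ## d_in 1 on a triangle-free graph: only edges or singletons
  ring <- as_network(edge_fixture(list(c("a", "b"), c("b", "c"), c("c", "d"),
                                       c("d", "a"))))
  cs2 <- cluster_network(ring, d_in = 1)
  expect_true(all(lengths(cs2$clusters) <= 2L))
  expect_setequal(unlist(cs2$clusters), ring$nodes)

  ## empty network: empty cluster set, coverage vacuously true
  empty <- as_network(edge_fixture(list(c("a", "b"))))
  empty$nodes <- character(0); empty$edges <- empty$edges[0, ]
  expect_length(cluster_network(empty, 0.5)$clusters, 0L)
})

test_that("extension against the original graph produces overlap", {
  ## two 6-cliques sharing nodes s1, s2: both output clusters contain the
  ## shared nodes even though the working graph deletes them after the first
  g <- graph_cliques(c(sprintf("a%d", 1:4), "s1", "s2"),
                     c(sprintf("b%d", 1:4), "s1", "s2"))
  cs <- cluster_network(g, d_in = 0.8, cp_in = 0.5)
  with_s <- vapply(cs$clusters, function(m) all(c("s1", "s2") %in% m), TRUE)
  expect_gte(sum(with_s), 2L)
  expect_setequal(unlist(cs$clusters), g$nodes)
})

test_that("clustering is deterministic and clusters satisfy their invariants", {
  sp <- simulation_spec(n_genes = 300L, n_background_nodes = 120L,
                        background_edge_prob = 0.04,
                        planted_modules = data.frame(size = c(8L, 8L, 10L),
                                                     intra_prob = c(1, 0.9, 0.7)),
                        n_disease_modules = 1L, known_disease_per_module = 3L,
                        hidden_disease_per_module = 2L, rng_seed = 5L)
  net <- as_network(simulate_network(sp, NULL)$edges)
  for (d_in in c(0.3, 0.6, 0.9)) {
    cs1 <- cluster_network(net, d_in, 0.5)
    cs2 <- cluster_network(net, d_in, 0.5)
    expect_identical(cs1$clusters, cs2$clusters)
    ## coverage
    expect_setequal(unlist(cs1$clusters), net$nodes)
    ## no duplicated member sets
    keys <- vapply(cs1$clusters, function(m) paste(sort(m), collapse = ","), "")
    expect_false(anyDuplicated(keys) > 0L)
    for (i in seq_along(cs1$clusters)) {
      mem <- cs1$clusters[[i]]
      d <- recount_density(net, mem)
      expect_equal(d, cs1$density[i], tolerance = 1e-12)
      if (length(mem) > 1L) expect_gte(d, d_in - 1e-9)
      expect_true(is_connected_subgraph(net, mem))
    }
  }
})

test_that("grid clustering yields one set per density and a consistent summary", {
  g <- graph_cliques(sprintf("a%d", 1:6), sprintf("b%d", 1:5),
                     extra = list(c("a1", "b1")))
  single <- cluster_grid(g, density_grid = 0.5)
  expect_length(single$sets, 1L)
  expect_equal(nrow(single$summary), 1L)

  grid <- cluster_grid(g, density_grid = seq(0.1, 0.9, 0.1))
  expect_length(grid$sets, 9L)
  expect_equal(nrow(grid$summary), 9L)
  ## arithmetic identity of the summary
  for (i in seq_along(grid$sets)) {
    sizes <- lengths(grid$sets[[i]]$clusters)
    expect_equal(grid$summary$avg_size[i], mean(sizes))
    expect_equal(grid$summary$max_size[i], max(sizes))
    expect_equal(grid$summary$n_clusters[i], length(sizes))
  }
})

test_that("planted cliques are recovered with high Jaccard overlap", {
  for (seed in c(1L, 2L, 3L)) {
    sp <- simulation_spec(n_genes = 300L, n_background_nodes = 160L,
                          background_edge_prob = 0.02,
                          planted_modules = data.frame(size = rep(8L, 5L),
                                                       intra_prob = 1),
                          n_disease_modules = 1L, known_disease_per_module = 3L,
                          hidden_disease_per_module = 2L, rng_seed = seed)
    sim <- simulate_network(sp, NULL)
    net <- as_network(sim$edges)
    cs <- cluster_network(net, d_in = 0.6, cp_in = 0.5)
    for (mem in sim$truth$module_members) {
      jac <- vapply(cs$clusters, function(cl)
        length(intersect(cl, mem)) / length(union(cl, mem)), 0)
      expect_gte(max(jac), 0.8)
    }
  }
})
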