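test_that("gene categorization follows the IDEG/ODEG/OG partition rule", {
  edges <- edge_fixture(list(c("A", "B"), c("B", "C"), c("C", "D")), 0.9)
  cat1 <- categorize_genes(deg_union = c("B", "C"), known = c("A", "B"),
                           edges = edges)
  got <- setNames(cat1$category, cat1$gene)
  ## A is known but not differentially expressed -> OG, not IDEG
  expect_equal(unname(got[c("A", "B", "C", "D")]),
               c("OG", "IDEG", "ODEG", "OG"))

  ## deg == known -> all IDEG, no ODEG
  cat2 <- categorize_genes(c("A", "B"), c("A", "B"), edges)
  expect_setequal(cat2$gene[cat2$category == "IDEG"], c("A", "B"))
  expect_length(cat2$gene[cat2$category == "ODEG"], 0L)

  ## empty IDEG set warns but still returns a partition
  expect_warning(categorize_genes("C", "Z", edges), "empty IDEG")

  ## synthetic truth: counts match generator bookkeeping
  sp <- simulation_spec(n_genes = 300L, n_background_nodes = 50L,
                        planted_modules = data.frame(size = rep(8L, 3L),
                                                     intra_prob = 1),
                        n_disease_modules = 2L, known_disease_per_module = 3L,
                        hidden_disease_per_module = 2L, rng_seed = 2L)
  net <- simulate_network(sp, NULL)
  deg <- unlist(net$truth$module_members)
  cat3 <- categorize_genes(deg, net$truth$known_disease_genes, net$edges)
  expect_equal(sum(cat3$category == "IDEG"), 6L)
  expect_equal(sum(cat3$category == "ODEG"), length(deg) - 6L)
})

test_that("edge filtering applies strict per-pair-type thresholds", {
  ## 12-edge fixture spanning all six unordered pair types; kept set
  ## enumerated by hand against the published threshold table
  ea <- c("I1", "I1", "I1", "I1", "D1", "D1", "D1", "D1", "O1", "I2", "D2", "I2")
  eb <- c("I2", "D1", "O1", "O2", "D2", "O1", "O2", "I2", "O2", "O1", "O1", "D2")
  cf <- c(0.10, 0.11, 0.72, 0.73, 0.05, 0.85, 0.86, 0.50, 0.99, 0.80, 0.90, 0.11)
  edges <- scored_edges(ea, eb, cf)
  cat <- categorize_genes(c("I1", "I2", "D1", "D2"), c("I1", "I2"), edges)
  net <- filter_edges(edges, cat)
  kept <- paste(net$edges$gene_a, net$edges$gene_b)
  ## hand enumeration:
  ##  I1-I2 0.10 IDEG-IDEG -> drop (not > 0.1)   I1-D1 0.11 IDEG-ODEG -> keep
  ##  I1-O1 0.72 IDEG-OG  -> drop (not > 0.72)   I1-O2 0.73 IDEG-OG  -> keep
  ##  D1-D2 0.05 ODEG-ODEG -> drop               D1-O1 0.85 ODEG-OG  -> drop
  ##  D1-O2 0.86 ODEG-OG  -> keep                D1-I2 0.50 IDEG-ODEG -> keep
  ##  O1-O2 0.99 OG-OG    -> always dropped      I2-O1 0.80 IDEG-OG  -> keep
  ##  D2-O1 0.90 ODEG-OG  -> keep                I2-D2 0.11 IDEG-ODEG -> keep
  expect_setequal(kept, c("D1 I1", "I1 O2", "D1 O2", "D1 I2",
                          "I2 O1", "D2 O1", "D2 I2"))
  expect_true(all(net$edges$pair_type != "OG-OG"))
  ## isolated nodes removed: every node has degree >= 1
  expect_setequal(net$nodes, unique(c(net$edges$gene_a, net$edges$gene_b)))

  ## all confidences 1, no OG-OG -> everything kept
  e2 <- scored_edges(c("I1", "I1"), c("I2", "D1"), c(1, 1))
  expect_equal(nrow(filter_edges(e2, cat)$edges), 2L)

  ## missing threshold for a needed pair type is a configuration error
  expect_error(filter_edges(edges, cat, c("IDEG-IDEG" = 0.1)),
               "no threshold configured")
})

test_that("raising thresholds never adds edges (monotonicity)", {
  set.seed(99)
  genes <- c(sprintf("I%d", 1:4), sprintf("D%d", 1:6), sprintf("O%d", 1:6))
  n <- 60L
  ea <- sample(genes, n, TRUE); eb <- sample(genes, n, TRUE)
  ok <- ea != eb
  edges <- scored_edges(ea[ok], eb[ok], runif(sum(ok)))
  cat <- categorize_genes(c(sprintf("I%d", 1:4), sprintf("D%d", 1:6)),
                          sprintf("I%d", 1:4), edges)
  types <- names(default_pair_thresholds())
  for (i in 1:50) {
    th1 <- setNames(runif(5), types)
    th2 <- th1
    bump <- sample(5L, sample(5L, 1))
    th2[bump] <- pmin(1, th2[bump] + runif(length(bump), 0, 0.5))
    k1 <- filter_edges(edges, cat, th1)$edges
    k2 <- filter_edges(edges, cat, th2)$edges
    expect_true(all(paste(k2$gene_a, k2$gene_b) %in% paste(k1$gene_a, k1$gene_b)))
  }
})

test_that("network reports match closed-form values on canonical graphs", {
  tri <- graph_triangle()
  r <- network_report(tri)
  expect_equal(r$clustering_coefficient, 1)
  expect_equal(r$diameter, 1)
  expect_equal(r$avg_path_length, 1)

  path <- as_network(edge_fixture(list(c("a", "b"), c("b", "c"))))
  rp <- network_report(path)
  expect_equal(rp$clustering_coefficient, 0)
  expect_equal(rp$diameter, 2)
  expect_equal(rp$avg_path_length, 4 / 3)

  star <- as_network(edge_fixture(list(c("h", "x"), c("h", "y"), c("h", "z"),
                                       c("h", "w"))))
  rs <- network_report(star)
  expect_equal(rs$clustering_coefficient, 0)
  expect_equal(rs$diameter, 2)

  ## path length/diameter computed on the largest component
  two_comp <- as_network(edge_fixture(list(c("a", "b"), c("b", "c"),
                                           c("x", "y"))))
  rt <- network_report(two_comp)
  expect_equal(rt$largest_component_size, 3)
  expect_equal(rt$diameter, 2)
})
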