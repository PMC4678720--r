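test_that("interaction loading deduplicates, drops self-loops and thresholds", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("node1\tnode2\tcombined_score",
               "a\tb\t900", "b\ta\t700", "a\ta\t999", "c\td\t150",
               "b\tc\t500"), f)
  g <- load_interactions(f, min_score = 400)
  expect_equal(igraph::ecount(g), 2)              # ab dedup, cd filtered, aa dropped
  eid <- igraph::get_edge_ids(g, c("a", "b"))
  expect_equal(igraph::E(g)$combined_score[eid], 900)  # max kept on merge
  expect_false("d" %in% igraph::V(g)$name)        # sub-threshold edge gone
  writeLines(c("node1\tnode2\tcombined_score", "a\t\t500"), f)
  expect_error(load_interactions(f), "malformed")
})

test_that("network density is observed over possible connections", {
  tri <- interaction_network(c("a", "b", "c"), c("b", "c", "a"), rep(900, 3))
  expect_equal(network_density(tri), 1)
  path <- interaction_network(c("a", "b"), c("b", "c"), c(900, 900))
  expect_equal(network_density(path), 2 / 3)
  iso <- igraph::make_empty_graph(10, directed = FALSE)
  expect_equal(network_density(iso), 0)
  expect_error(network_density(igraph::make_empty_graph(1, directed = FALSE)),
               "at least 2")
})

test_that("the simulated density null matches closed-form expectations", {
  # complete graph: every induced subgraph has density 1
  cg <- igraph::make_full_graph(12)
  igraph::V(cg)$name <- paste0("v", 1:12)
  null <- simulate_null_density(cg, paste0("v", 1:12), m = 5, reps = 50, seed = 1)
  expect_true(all(null$densities == 1))

  # empty graph: all densities 0
  eg <- igraph::make_empty_graph(12, directed = FALSE)
  igraph::V(eg)$name <- paste0("v", 1:12)
  null0 <- simulate_null_density(eg, paste0("v", 1:12), m = 5, reps = 50, seed = 1)
  expect_true(all(null0$densities == 0))

  # Erdos-Renyi G(200, 0.05): every edge survives into an m-subset with the
  # same probability, so E[induced density | graph] is the graph's own
  # density; the realized graph density is itself within binomial noise of p
  pp <- generate_planted_partition(200, 0.05, 0.05, seed = 3)
  dg <- network_density(pp$graph)
  expect_lt(abs(dg - 0.05), 4 * sqrt(0.05 * 0.95 / choose(200, 2)))
  null2 <- simulate_null_density(pp$graph, names(pp$membership), m = 50,
                                 reps = 2000, seed = 5)
  se <- sd(null2$densities) / sqrt(null2$reps)
  expect_lt(abs(mean(null2$densities) - dg), 3 * se)

  # universe genes missing from the network dilute the density
  null3 <- simulate_null_density(cg, c(paste0("v", 1:12), paste0("x", 1:12)),
                                 m = 8, reps = 200, seed = 2)
  expect_lt(mean(null3$densities), 1)
  expect_error(simulate_null_density(cg, paste0("v", 1:12), m = 1), ">= 2")
})

test_that("Box-Cox profile likelihood recovers canonical lambdas", {
  set.seed(51)
  bn <- boxcox_transform(rnorm(10000, mean = 50, sd = 2))
  expect_lt(abs(bn$lambda - 1), 0.3)
  bl <- boxcox_transform(exp(rnorm(10000)))
  expect_lt(abs(bl$lambda), 0.15)
  # lambda = 1 is an affine map
  x <- c(1.5, 2, 4, 8, 3, 2.2, 5, 6, 7, 9)
  y <- ((x + 0)^1 - 1) / 1
  expect_equal(y, x - 1)
  expect_error(boxcox_transform(rep(3, 20)), "constant")
})

test_that("density p-values are centered and directional", {
  pp <- generate_planted_partition(150, 0.08, 0.08, seed = 13)
  null <- simulate_null_density(pp$graph, names(pp$membership), m = 40,
                                reps = 2000, seed = 7)
  expect_equal(density_pvalue(mean(null$densities), null), 0.5,
               tolerance = 0.05)
  expect_lt(density_pvalue(max(null$densities) + 10 * sd(null$densities), null),
            0.01)
})

test_that("Louvain recovers obvious community structure", {
  # two 6-cliques joined by a single edge
  g <- igraph::disjoint_union(igraph::make_full_graph(6),
                              igraph::make_full_graph(6))
  g <- igraph::add_edges(g, c(1, 7))
  igraph::V(g)$name <- paste0("v", 1:12)
  part <- louvain_modules(g, seed = 3)
  expect_identical(length(part$sizes), 2L)
  expect_identical(length(unique(part$membership[1:6])), 1L)
  expect_identical(length(unique(part$membership[7:12])), 1L)

  single <- igraph::make_full_graph(8)
  igraph::V(single)$name <- paste0("v", 1:8)
  expect_identical(length(louvain_modules(single, seed = 1)$sizes), 1L)

  # modularity at least that of the trivial one-module partition
  pp <- generate_planted_partition(c(20, 20, 20), 0.4, 0.05, seed = 5)
  part2 <- louvain_modules(pp$graph, seed = 2)
  triv <- igraph::modularity(pp$graph,
                             rep(1, igraph::vcount(pp$graph)))
  expect_gte(part2$modularity, triv)
})

test_that("module reports expose size, density, null p and degrees", {
  # a triangle plus a star K1,5, joined sparsely
  edges <- rbind(c("t1", "t2"), c("t2", "t3"), c("t1", "t3"),
                 c("hub", "s1"), c("hub", "s2"), c("hub", "s3"),
                 c("hub", "s4"), c("hub", "s5"), c("t1", "hub"))
  g <- interaction_network(edges[, 1], edges[, 2], rep(900, nrow(edges)))
  memb <- setNames(c(1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L, 2L, 3L),
                   c("t1", "t2", "t3", "hub", "s1", "s2", "s3", "s4", "s5", "lonely"))
  part <- structure(list(membership = memb, sizes = c(3L, 6L, 1L),
                         modularity = NA_real_, seed = 1L),
                    class = "module_partition")
  g <- igraph::add_vertices(g, 1, name = "lonely")
  rep_ <- module_report(g, part, universe = names(memb), reps = 200, seed = 2)
  m1 <- rep_$modules[rep_$modules$module == 1, ]
  expect_equal(m1$density, 1)       # triangle
  expect_false(m1$excluded)
  expect_true(rep_$modules$excluded[rep_$modules$module == 3])  # singleton
  deg <- rep_$degrees
  expect_identical(deg$degree[deg$gene == "hub"], 6L)
  expect_true(all(deg$degree[deg$gene %in% paste0("s", 1:5)] == 1L))
})
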