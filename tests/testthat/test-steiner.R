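test_that("node-weighted shortest paths exclude source and region weights", {
  g <- graph_from_pairs("s", "r", "s", "w1", "w1", "r2", "r2", "x")
  inst <- steiner_instance(g, c("s", "r"), node_weights = c(w1 = 1, r2 = 1, x = 1))
  adjacent <- node_weighted_shortest_path(inst, "s", "r")
  expect_equal(adjacent$cost, 0)
  expect_length(adjacent$path, 2L)

  one_linker <- node_weighted_shortest_path(inst, "s", "r2")
  expect_equal(one_linker$cost, 1) # pays w1 only; r2 is in the region
  expect_equal(one_linker$path, c("s", "w1", "r2"))

  inside <- node_weighted_shortest_path(inst, "s", c("s", "r"))
  expect_equal(inside$cost, 0)

  unreachable <- steiner_instance(graph_from_pairs("a", "b", "c", "d"), c("a", "c"))
  expect_equal(node_weighted_shortest_path(unreachable, "a", "c")$cost, Inf)
})

test_that("cheaper single linker beats two unit linkers", {
  # two routes from s to t: s-u-v-t (cost 2) vs s-m-t (cost 1.5)
  g <- graph_from_pairs("s", "u", "u", "v", "v", "t", "s", "m", "m", "t")
  inst <- steiner_instance(g, c("s", "t"), node_weights = c(u = 1, v = 1, m = 1.5))
  sp <- node_weighted_shortest_path(inst, "s", "t")
  expect_equal(sp$cost, 1.5)
  expect_equal(sp$path, c("s", "m", "t"))
  # exhaustive check: all simple paths
  all_paths <- igraph::all_simple_paths(g, "s", "t")
  costs <- vapply(all_paths, function(p) {
    inner <- setdiff(names(p), c("s", "t"))
    sum(c(u = 1, v = 1, m = 1.5)[inner], na.rm = TRUE)
  }, 0)
  expect_equal(sp$cost, min(costs))
})

test_that("terminals already connected need no linkers; a forced linker is added", {
  g <- graph_from_pairs("t1", "t2", "t2", "t3", "t3", "x")
  inst <- steiner_instance(g, c("t1", "t2", "t3"))
  expect_setequal(klein_ravi(inst), c("t1", "t2", "t3"))

  g2 <- graph_from_pairs("T1", "L", "L", "T2")
  expect_setequal(klein_ravi(steiner_instance(g2, c("T1", "T2"))), c("T1", "L", "T2"))
})

test_that("disconnected terminal groups return one tree per group with a warning", {
  g <- graph_from_pairs("a1", "x", "x", "a2", "b1", "b2")
  inst <- steiner_instance(g, c("a1", "a2", "b1", "b2"))
  expect_warning(nodes <- klein_ravi(inst), "disconnected")
  expect_setequal(nodes, c("a1", "a2", "x", "b1", "b2"))
})

test_that("klein_ravi respects the 2 ln(k) bound against the exact optimum and is minimal", {
  set.seed(77)
  n_checked <- 0L
  for (i in 1:25) {
    g <- random_connected_graph(sample(8:12, 1), stats::runif(1, 0.2, 0.4))
    terminals <- sample(igraph::V(g)$name, sample(3:5, 1))
    inst <- steiner_instance(g, terminals)
    nodes <- klein_ravi(inst)
    expect_true(all(terminals %in% nodes))
    linker_weight <- length(setdiff(nodes, terminals))
    opt <- exact_steiner_optimum(g, terminals, inst$weights)
    expect_lte(linker_weight, max(2 * log(length(terminals)) * opt, opt))
    # minimality: every surviving linker disconnects some terminal pair
    for (l in setdiff(nodes, terminals)) {
      h <- igraph::induced_subgraph(g, setdiff(nodes, l))
      comp <- igraph::components(h)$membership
      expect_gt(length(unique(comp[terminals])), 1L)
    }
    n_checked <- n_checked + 1L
  }
  expect_equal(n_checked, 25L)
})

test_that("klein_ravi is deterministic on identical input", {
  set.seed(5)
  g <- random_connected_graph(12, 0.25)
  terminals <- sample(igraph::V(g)$name, 4)
  inst <- steiner_instance(g, terminals)
  expect_identical(klein_ravi(inst), klein_ravi(inst))
})

test_that("induced subnetworks carry all induced edges, roles and categories", {
  g <- graph_from_pairs(
    "a1", "a2", "a1", "b1", "b1", "l1", "a2", "l1", "a1", "z"
  )
  sn <- induced_subnetwork(g, c("a1", "a2", "b1", "l1"), c("a1", "a2"), "b1")
  expect_equal(nrow(sn$edges), 4L) # the a1-z edge is outside
  comp <- edge_composition(sn)
  expect_equal(unname(comp$counts), c(1L, 0L, 1L, 2L))
  # tree edges are a subset of induced edges, acyclic, spanning
  tree <- sn$edges[sn$edges$in_tree, ]
  expect_equal(nrow(tree), 3L)
  ht <- igraph::graph_from_data_frame(tree[, 1:2], directed = FALSE)
  expect_true(igraph::is_tree(ht))

  # terminals-only subnetwork has no linker-involving edges
  sn2 <- induced_subnetwork(g, c("a1", "a2", "b1"), c("a1", "a2"), "b1")
  expect_equal(unname(edge_composition(sn2)$counts["linker-involving"]), 0L)

  expect_error(
    induced_subnetwork(g, c("a1", "b1"), c("a1"), c("a1", "b1")),
    class = "oncotopo_steiner"
  )
  perm <- induced_subnetwork(g, c("a1", "b1"), "a1", c("a1", "b1"), strict = FALSE)
  expect_true("terminal-A+B" %in% perm$nodes$role)
})

test_that("edge composition reproduces exact arithmetic from counts", {
  comp <- edge_composition(c("A-A" = 2L, "B-B" = 1L, "A-B" = 3L, "linker-involving" = 1L))
  expect_equal(comp$total_edges, 7L)
  expect_equal(comp$among_terminal_count, 6L)
  expect_equal(comp$among_terminal_percent, 85.7)
  empty <- edge_composition(c("A-A" = 0L))
  expect_equal(empty$total_edges, 0L)
  expect_equal(sum(empty$proportions), 0)
})

test_that("composition counts sum to the edge count and ignore edge order", {
  study <- toy_study(seed = 31L, n_nodes = 150L)
  inst <- steiner_instance(study$network, union(study$sets$TSG, study$sets$OCG), quiet = TRUE)
  sn <- induced_subnetwork(
    study$network, klein_ravi(inst), study$sets$TSG, study$sets$OCG
  )
  comp <- edge_composition(sn)
  expect_equal(sum(comp$counts), nrow(sn$edges))
  sn_shuffled <- sn
  sn_shuffled$edges <- sn$edges[sample.int(nrow(sn$edges)), ]
  expect_equal(edge_composition(sn_shuffled)$counts, comp$counts)
  expect_equal(sum(comp$proportions), 100, tolerance = 0.2)
})

test_that("mutation frequencies attach without disturbing node or edge sets", {
  g <- graph_from_pairs("TP53", "PTEN", "PTEN", "KRAS")
  cat <- build_catalog(g, list(TSG = c("TP53", "PTEN"), OCG = "KRAS", Target = "TP53", Essential = "KRAS"))
  tab <- toy_mutation_table()
  prof <- suppressWarnings(set_frequency_profile(tab, cat))
  sn <- induced_subnetwork(g, c("TP53", "PTEN", "KRAS"), c("TP53", "PTEN"), "KRAS")
  sn2 <- attach_mutation_frequency(sn, prof, quiet = TRUE)
  expect_equal(sn2$nodes$node, sn$nodes$node)
  expect_equal(sn2$edges, sn$edges)
  expect_equal(
    sn2$nodes$mutation_frequency[sn2$nodes$node == "TP53"],
    gene_mutation_frequency(tab, "TP53")
  )
})

test_that("degree-frequency correlation hits closed-form and degenerate cases", {
  g <- graph_from_pairs("h", "x", "h", "y", "h", "z", "x", "y")
  sn <- induced_subnetwork(g, c("h", "x", "y", "z"), c("h", "x"), c("y", "z"))
  deg <- igraph::degree(subnetwork_graph(sn))[sn$nodes$node]
  sn$nodes$mutation_frequency <- as.numeric(10 * deg)
  r <- degree_frequency_correlation(sn)
  expect_equal(r$r, 1)

  sn$nodes$mutation_frequency <- rep(5, 4)
  flat <- degree_frequency_correlation(sn)
  expect_true(is.na(flat$r))
})

test_that("t-based p-value agrees with the permutation distribution", {
  study <- toy_study(seed = 41L, n_nodes = 200L)
  cat <- suppressMessages(build_catalog(study$network, study$sets))
  prof <- set_frequency_profile(study$table, cat)
  inst <- steiner_instance(study$network, union(study$sets$TSG, study$sets$OCG), quiet = TRUE)
  sn <- induced_subnetwork(study$network, klein_ravi(inst), study$sets$TSG, study$sets$OCG)
  sn <- attach_mutation_frequency(sn, prof, quiet = TRUE)
  rt <- degree_frequency_correlation(sn, p_method = "t")
  rp <- degree_frequency_correlation(sn, p_method = "permutation", n_permutations = 2000, seed = 1)
  expect_equal(rt$r, rp$r)
  expect_lt(abs(rt$p_value - rp$p_value), 0.05)
})
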