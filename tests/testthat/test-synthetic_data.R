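test_that("preferential attachment yields the documented edge count and heavy tail", {
  g <- generate_network(synthetic_spec(n_nodes = 100, pa_m = 2, seed = 1))
  expect_equal(igraph::vcount(g), 100L)
  expect_equal(igraph::ecount(g), 2 * (100 - 2) + 1) # m(n-m) + m - 1
  g3 <- generate_network(synthetic_spec(n_nodes = 500, pa_m = 3, seed = 2))
  expect_equal(igraph::ecount(g3), 3 * 497 + 2)
  deg <- igraph::degree(g3)
  expect_gte(max(deg), 3 * stats::median(deg))
})

test_that("generators are seed-deterministic and distinct seeds differ", {
  s <- synthetic_spec(n_nodes = 120, pa_m = 2, seed = 9)
  e1 <- igraph::as_edgelist(generate_network(s))
  e2 <- igraph::as_edgelist(generate_network(s))
  expect_identical(e1, e2)
  s2 <- synthetic_spec(n_nodes = 120, pa_m = 2, seed = 10)
  expect_false(identical(e1, igraph::as_edgelist(generate_network(s2))))
})

test_that("generator calls leave the caller's RNG stream untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_network(synthetic_spec(n_nodes = 50, seed = 4)))
  expect_identical(.Random.seed, before)
})

test_that("invalid model parameters error, including an empty ER draw", {
  expect_error(synthetic_spec(n_nodes = 1), class = "oncotopo_spec")
  expect_error(synthetic_spec(n_nodes = 10, pa_m = 10), class = "oncotopo_spec")
  expect_error(synthetic_spec(er_p = 2), class = "oncotopo_spec")
  spec <- synthetic_spec(n_nodes = 20, model = "erdos-renyi", er_p = 0, seed = 1)
  expect_error(generate_network(spec), class = "oncotopo_empty_network")
})

test_that("duplication-divergence builds a connected-ish simple network", {
  g <- generate_network(synthetic_spec(
    n_nodes = 200, model = "duplication-divergence",
    dd_retention = 0.5, seed = 3
  ))
  expect_equal(igraph::vcount(g), 200L)
  expect_true(igraph::is_simple(g))
})

test_that("planted sets are disjoint by default and uniform at alpha 0", {
  spec <- synthetic_spec(n_nodes = 400, pa_m = 2, seed = 8)
  net <- generate_network(spec)
  sets <- plant_gene_sets(net, spec$set_specs, seed = 1)
  for (p in utils::combn(names(sets), 2, simplify = FALSE)) {
    expect_length(intersect(sets[[p[1]]], sets[[p[2]]]), 0L)
  }
  # alpha = 0 sampling is unbiased: mean planted degree ~ network mean
  deg <- igraph::degree(net)
  means <- vapply(1:100, function(s) {
    picked <- plant_gene_sets(net,
      tibble::tibble(name = "U", size = 40L, alpha = 0, rate = 0),
      seed = s
    )$U
    mean(deg[picked])
  }, 0)
  expect_lt(abs(mean(means) - mean(deg)), 3 * stats::sd(means) / sqrt(100))
})

test_that("alpha 2 planting on a scale-free network biases toward hubs", {
  hits <- vapply(1:60, function(s) {
    spec <- synthetic_spec(n_nodes = 300, pa_m = 2, seed = s)
    net <- generate_network(spec)
    deg <- igraph::degree(net)
    picked <- plant_gene_sets(net,
      tibble::tibble(name = "H", size = 30L, alpha = 2, rate = 0),
      seed = s + 500L
    )$H
    mean(deg[picked]) > mean(deg)
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("overlap planting shares the requested fraction", {
  specs <- tibble::tibble(
    name = c("TSG", "OCG"), size = c(30L, 30L), alpha = c(1, 0), rate = 0.01
  )
  net <- generate_network(synthetic_spec(n_nodes = 300, pa_m = 2, seed = 2))
  sets <- plant_gene_sets(net, specs, seed = 3, overlap_fraction = 0.2)
  expect_length(intersect(sets$OCG, sets$TSG), round(0.2 * 30))
})

test_that("infeasible planting sizes error", {
  net <- generate_network(synthetic_spec(n_nodes = 20, pa_m = 2, seed = 1))
  expect_error(
    plant_gene_sets(net, tibble::tibble(name = "X", size = 21L, alpha = 0, rate = 0), seed = 1),
    class = "oncotopo_spec"
  )
})

test_that("rate 0 yields no records and rate 1 yields frequency 100", {
  base <- synthetic_spec(
    n_nodes = 30,
    set_specs = tibble::tibble(name = c("TSG", "OCG", "Target", "Essential"),
                               size = c(5L, 5L, 5L, 5L), alpha = 0,
                               rate = c(0, 1, 0, 0)),
    background_rate = 0,
    tumor_types = tibble::tibble(tumor_type = "BRCA", n_samples = 20L, multiplier = 1),
    seed = 6
  )
  study <- synthetic_study(base)
  tab <- study$table
  expect_length(intersect(unique(tab$records$gene), study$sets$TSG), 0L)
  for (gene in study$sets$OCG) {
    expect_equal(gene_mutation_frequency(tab, gene), 100)
  }
  expect_equal(nrow(tab$samples), 20L)
})

test_that("rate-multiplier products above 1 are clamped with a warning", {
  spec <- synthetic_spec(
    n_nodes = 20,
    set_specs = tibble::tibble(name = c("TSG", "OCG", "Target", "Essential"),
                               size = c(2L, 2L, 2L, 2L), alpha = 0, rate = c(0.9, 0, 0, 0)),
    tumor_types = tibble::tibble(tumor_type = "BRCA", n_samples = 5L, multiplier = 2),
    seed = 2
  )
  sets <- plant_gene_sets(generate_network(spec), spec$set_specs, seed = 3)
  expect_warning(simulate_mutations(sets, spec, seed = 4), "clamped")
})

test_that("full synthetic pipeline recovers joint rate and degree-bias ordering", {
  hits <- vapply(1:20, function(s) {
    study <- toy_study(seed = 6000L + s, n_nodes = 250L)
    cat <- suppressMessages(build_catalog(study$network, study$sets))
    prof <- suppressWarnings(set_frequency_profile(study$table, cat))
    means <- setNames(
      prof$per_set$mean_frequency[prof$per_set$stratum == "ALL"],
      prof$per_set$set[prof$per_set$stratum == "ALL"]
    )
    deg <- igraph::degree(study$network)
    freq_ok <- means["TSG"] > means["OCG"] && means["OCG"] > means["Other"]
    deg_ok <- mean(deg[study$sets$TSG]) > mean(deg[study$sets$OCG]) &&
      mean(deg[study$sets$OCG]) > mean(deg[cat$mapped$Other])
    freq_ok && deg_ok
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("written synthetic studies read back identically", {
  dir <- withr::local_tempdir()
  spec <- synthetic_spec(n_nodes = 80, pa_m = 2, seed = 5,
    set_specs = tibble::tibble(name = c("TSG", "OCG", "Target", "Essential"),
                               size = c(10L, 10L, 10L, 10L), alpha = c(1, 0, 0, 0),
                               rate = c(0.05, 0.01, 0.01, 0.01)))
  paths <- write_synthetic_study(spec, dir)
  study <- synthetic_study(spec)
  net <- suppressMessages(read_interactions(paths[["network"]], format = "tsv", header = FALSE))
  expect_equal(igraph::ecount(net), igraph::ecount(study$network))
  sets <- read_gene_list(paths[["sets"]], format = "gmt")
  expect_identical(lapply(sets, sort), lapply(study$sets, sort))
  tab <- read_mutation_table(paths[["mutations"]], manifest = paths[["manifest"]])
  expect_equal(nrow(tab$records), nrow(study$table$records))
  expect_equal(nrow(tab$samples), nrow(study$table$samples))
})
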