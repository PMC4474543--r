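test_that("gene frequency counts each mutated sample once against manifest denominators", {
  tab <- toy_mutation_table()
  # s1 has two TP53 records but counts once; 5 samples total
  expect_equal(gene_mutation_frequency(tab, "TP53", "ALL"), 100 * 2 / 5)
  expect_equal(gene_mutation_frequency(tab, "ABSENT", "ALL"), 0)
  expect_equal(gene_mutation_frequency(tab, "TP53", "BRCA"), 100 * 2 / 3)
  expect_error(gene_mutation_frequency(tab, "TP53", "NOPE"), class = "oncotopo_stratum")
})

test_that("a 6-of-13 gene prints as 46.15 percent", {
  records <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:6), gene = "TP53",
    tumor_type = "BRCA", variant_class = "Missense_Mutation"
  )
  samples <- tibble::tibble(sample_id = sprintf("s%02d", 1:13), tumor_type = "BRCA")
  tab <- mutation_table(records, samples)
  expect_equal(round(gene_mutation_frequency(tab, "TP53"), 2), 46.15)
})

test_that("the non-silent filter drops silent records", {
  tab <- toy_mutation_table()
  expect_equal(gene_mutation_frequency(tab, "KRAS", "ALL"), 20)
  expect_equal(gene_mutation_frequency(tab, "KRAS", "ALL", nonsilent_only = TRUE), 0)
})

test_that("set means are arithmetic means including zero-mutation members", {
  g <- graph_from_pairs("TP53", "PTEN", "PTEN", "KRAS", "KRAS", "EGFR", "EGFR", "ZZ1")
  cat <- build_catalog(g, list(
    TSG = c("TP53", "PTEN"), OCG = "KRAS", Target = "EGFR", Essential = "ZZ1"
  ))
  tab <- toy_mutation_table()
  prof <- suppressWarnings(set_frequency_profile(tab, cat))
  f <- set_frequencies(prof, "TSG")
  expect_equal(unname(f[c("TP53", "PTEN")]), c(40, 20))
  expect_equal(
    prof$per_set$mean_frequency[prof$per_set$set == "TSG" & prof$per_set$stratum == "ALL"],
    30
  )
  # EGFR and ZZ1 have no records: present as zeros
  expect_equal(unname(set_frequencies(prof, "Target")), 0)
  # per-set mean recomputable from the member list in every stratum
  for (s in unique(prof$per_set$stratum)) {
    for (nm in unique(prof$membership$set)) {
      expect_equal(
        prof$per_set$mean_frequency[prof$per_set$set == nm & prof$per_set$stratum == s],
        mean(set_frequencies(prof, nm, s))
      )
    }
  }
})

test_that("frequencies are invariant to record order and duplicated records", {
  tab <- toy_mutation_table()
  shuffled <- mutation_table(tab$records[sample.int(nrow(tab$records)), ], tab$samples)
  duplicated_tab <- mutation_table(
    dplyr::bind_rows(tab$records, tab$records), tab$samples
  )
  for (t2 in list(shuffled, duplicated_tab)) {
    expect_equal(
      gene_mutation_frequency(t2, "TP53", "ALL"),
      gene_mutation_frequency(tab, "TP53", "ALL")
    )
  }
})

test_that("ALL frequency is the sample-count-weighted mean of per-type frequencies", {
  study <- toy_study(seed = 5L, n_nodes = 200L)
  tab <- study$table
  denom <- dplyr::count(tab$samples, tumor_type)
  for (gene in unique(tab$records$gene)[1:5]) {
    per_type <- vapply(denom$tumor_type, function(tt) {
      gene_mutation_frequency(tab, gene, tt)
    }, 0)
    expect_equal(
      gene_mutation_frequency(gene = gene, table = tab),
      sum(per_type * denom$n) / sum(denom$n)
    )
  }
})

test_that("simulated frequencies recover the planted rate within binomial error", {
  spec <- synthetic_spec(
    n_nodes = 60,
    set_specs = tibble::tibble(name = c("TSG", "OCG", "Target", "Essential"),
                               size = c(20L, 5L, 5L, 5L), alpha = 0,
                               rate = c(0.05, 0.01, 0.01, 0.01)),
    tumor_types = tibble::tibble(tumor_type = "BRCA", n_samples = 500L, multiplier = 1),
    seed = 42L
  )
  study <- synthetic_study(spec)
  cat <- suppressMessages(build_catalog(study$network, study$sets))
  prof <- set_frequency_profile(study$table, cat)
  m <- prof$per_set$mean_frequency[prof$per_set$set == "TSG" & prof$per_set$stratum == "ALL"]
  se <- 100 * sqrt(0.05 * 0.95 / (500 * 20))
  expect_lt(abs(m - 5), 3 * se)
})

test_that("single-type tables stratify identically to ALL", {
  records <- tibble::tibble(
    sample_id = c("s1", "s2"), gene = c("TP53", "PTEN"),
    tumor_type = "BRCA", variant_class = "Missense_Mutation"
  )
  tab <- mutation_table(records)
  g <- graph_from_pairs("TP53", "PTEN")
  cat <- build_catalog(g, list(TSG = "TP53", OCG = "PTEN", Target = "TP53", Essential = "PTEN"))
  prof <- suppressWarnings(set_frequency_profile(tab, cat))
  wide <- tidyr::pivot_wider(prof$per_gene, names_from = stratum, values_from = frequency)
  expect_equal(wide$ALL, wide$BRCA)
})

test_that("K-S statistic matches hand-enumerable cases and errors on empty input", {
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(ks_two_sample(c(1, 2), c(10, 20))$statistic, 1)
  expect_equal(ks_two_sample(c(1, 3), c(2, 4))$statistic, 0.5)
  expect_error(ks_two_sample(numeric(0), 1), class = "oncotopo_ks")
})

test_that("K-S statistic equals the brute-force ECDF sup-difference on random pairs", {
  set.seed(99)
  for (i in 1:200) {
    x <- round(stats::rexp(sample(1:30, 1), 0.2), 1) # rounding forces ties
    y <- round(stats::rnorm(sample(1:30, 1), 2, 2), 1)
    expect_equal(ks_two_sample(x, y)$statistic, brute_ks_statistic(x, y), tolerance = 1e-12)
  }
})

test_that("K-S p-value decreases as D grows at fixed sample sizes", {
  shift <- c(0.2, 0.6, 1.4, 3)
  set.seed(1)
  x <- stats::rnorm(60)
  res <- lapply(shift, function(s) ks_two_sample(x, x + s))
  d <- vapply(res, `[[`, 0, "statistic")
  p <- vapply(res, `[[`, 0, "p_value")
  expect_true(all(diff(d) >= 0))
  expect_true(all(diff(p) <= 0))
})

test_that("compare_sets yields a symmetric matrix with zero diagonal and untestable flags", {
  g <- graph_from_pairs("a", "b", "b", "c", "c", "d")
  cat <- build_catalog(g, list(TSG = c("a", "b"), OCG = c("c", "d"), Target = "a", Essential = "b"))
  records <- tibble::tibble(
    sample_id = c("s1", "s1", "s2"), gene = c("a", "b", "a"),
    tumor_type = "BRCA", variant_class = "Missense_Mutation"
  )
  tab <- mutation_table(records, tibble::tibble(
    sample_id = c("s1", "s2"), tumor_type = "BRCA"
  ))
  prof <- suppressWarnings(set_frequency_profile(tab, cat))
  cmp <- compare_sets(prof)
  m <- ks_matrix(cmp)
  expect_equal(unname(diag(m)), rep(0, nrow(m)))
  expect_equal(m, t(m))
  # identical frequency lists -> D = 0, asymptotic p = 1
  same <- ks_two_sample(set_frequencies(prof, "TSG"), set_frequencies(prof, "TSG"))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
})

test_that("planted high-rate vs low-rate sets are separated with high power", {
  hits <- vapply(1:40, function(seed) {
    spec <- synthetic_spec(
      n_nodes = 110,
      set_specs = tibble::tibble(
        name = c("TSG", "OCG", "Target", "Essential"),
        size = c(50L, 50L, 5L, 5L), alpha = 0,
        rate = c(0.05, 0.01, 0.01, 0.01)
      ),
      tumor_types = tibble::tibble(tumor_type = "BRCA", n_samples = 500L, multiplier = 1),
      seed = 1000L + seed
    )
    study <- synthetic_study(spec)
    cat <- suppressMessages(build_catalog(study$network, study$sets))
    prof <- suppressWarnings(set_frequency_profile(study$table, cat))
    ks_two_sample(set_frequencies(prof, "TSG"), set_frequencies(prof, "OCG"))$p_value < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})
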