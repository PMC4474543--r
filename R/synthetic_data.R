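#' Specification for a synthetic study
#'
#' Bundles the generator parameters for a network, planted gene sets and a
#' somatic-mutation table with the statistical structure the analysis
#' assumes: a sparse scale-free interaction network, gene sets with
#' controllable hub bias (sampling weight proportional to degree^alpha), and
#' per-sample Bernoulli mutations with set-specific rates modulated by
#' tumor-type multipliers. Defaults describe the study-scale conditions used
#' throughout the package: a 1,000-node preferential-attachment network, the
#' four canonical sets at the field's catalog sizes with a 5% / 1% / 0.5% /
#' 0.2% rate ladder over a 0.2% background, and ~500 tumor samples spread
#' over the 12 Pan-Cancer tumor types with the highest-burden type (UCEC)
#' boosted and the lowest (LAML) damped.
#'
#' @param n_nodes network size (>= 2).
#' @param model `"preferential-attachment"` (default),
#'   `"duplication-divergence"` or `"erdos-renyi"`.
#' @param pa_m attachment edges per new node (preferential attachment).
#' @param dd_retention per-edge retention probability (duplication-divergence).
#' @param er_p edge probability (Erdős–Rényi).
#' @param set_specs tibble with columns `name`, `size`, `alpha` (degree-bias
#'   exponent >= 0) and `rate` (per-sample per-gene mutation probability).
#' @param background_rate mutation rate for genes outside every set.
#' @param tumor_types tibble with columns `tumor_type`, `n_samples`,
#'   `multiplier` (rate multiplier for samples of that type).
#' @param overlap_fraction fraction of each planted set (after the first)
#'   drawn from previously planted genes, to exercise overlap accounting;
#'   default 0 (disjoint sets).
#' @param seed integer seed; identical spec + seed gives byte-identical
#'   outputs.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_nodes = 1000L,
                           model = c("preferential-attachment", "duplication-divergence", "erdos-renyi"),
                           pa_m = 3L,
                           dd_retention = 0.4,
                           er_p = 0.01,
                           set_specs = default_set_specs(),
                           background_rate = 0.002,
                           tumor_types = default_tumor_type_spec(),
                           overlap_fraction = 0,
                           seed = 1L) {
  model <- match.arg(model)
  if (n_nodes < 2L) oncotopo_abort("n_nodes must be >= 2", "spec")
  if (model == "preferential-attachment" && (pa_m < 1L || pa_m >= n_nodes)) {
    oncotopo_abort("pa_m must satisfy 1 <= pa_m < n_nodes", "spec")
  }
  if (er_p < 0 || er_p > 1) oncotopo_abort("er_p must be in [0, 1]", "spec")
  if (dd_retention < 0 || dd_retention > 1) oncotopo_abort("dd_retention must be in [0, 1]", "spec")
  set_specs <- as_tibble(set_specs)
  stopifnot(all(c("name", "size", "alpha", "rate") %in% names(set_specs)))
  if (any(set_specs$alpha < 0)) oncotopo_abort("alpha must be >= 0", "spec")
  if (any(set_specs$rate < 0 | set_specs$rate > 1) || background_rate < 0 || background_rate > 1) {
    oncotopo_abort("mutation rates must be in [0, 1]", "spec")
  }
  tumor_types <- as_tibble(tumor_types)
  stopifnot(all(c("tumor_type", "n_samples", "multiplier") %in% names(tumor_types)))
  if (any(tumor_types$n_samples < 1L)) oncotopo_abort("sample counts must be >= 1", "spec")
  structure(
    list(
      n_nodes = as.integer(n_nodes), model = model, pa_m = as.integer(pa_m),
      dd_retention = dd_retention, er_p = er_p, set_specs = set_specs,
      background_rate = background_rate, tumor_types = tumor_types,
      overlap_fraction = overlap_fraction, seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

#' @rdname synthetic_spec
#' @export
default_set_specs <- function() {
  tibble(
    name = c("TSG", "OCG", "Target", "Essential"),
    size = c(50L, 50L, 150L, 140L),
    alpha = c(2, 1, 0.5, 0.5),
    rate = c(0.05, 0.01, 0.005, 0.002)
  )
}

#' @rdname synthetic_spec
#' @export
default_tumor_type_spec <- function() {
  v <- tumor_type_vocabulary()
  tibble(
    tumor_type = v,
    n_samples = 42L,
    multiplier = dplyr::case_when(v == "UCEC" ~ 1.5, v == "LAML" ~ 0.3, TRUE ~ 1)
  )
}

synthetic_symbols <- function(n) sprintf("G%06d", seq_len(n))

#' Generate a synthetic interaction network
#'
#' Preferential attachment starts from a path of `pa_m` seed nodes and
#' attaches each subsequent node to `pa_m` distinct existing nodes sampled
#' proportionally to degree, giving exactly `pa_m * (n - pa_m) + pa_m - 1`
#' edges and a heavy-tailed degree distribution. Duplication-divergence
#' copies a random anchor's neighborhood, retaining each edge independently
#' (falling back to the anchor itself when nothing is retained).
#' Erdős–Rényi is the G(n, p) model.
#'
#' @param spec a [synthetic_spec()].
#' @return an undirected simple `igraph` with synthetic symbols
#'   (`G000001`, ...) as node names.
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_nodes
  with_seed(spec$seed, {
    if (spec$model == "preferential-attachment") {
      m <- spec$pa_m
      from <- integer(0)
      to <- integer(0)
      if (m > 1L) {
        from <- seq_len(m - 1L)
        to <- seq_len(m - 1L) + 1L
      }
      deg <- integer(n)
      deg[seq_len(m)] <- tabulate(c(from, to), nbins = n)[seq_len(m)]
      if (m == 1L) deg[1L] <- 1L # virtual mass so the first draw is defined
      for (i in seq.int(m + 1L, n)) {
        existing <- seq_len(i - 1L)
        targets <- if (length(existing) == m) {
          existing
        } else {
          sample(existing, m, prob = deg[existing])
        }
        from <- c(from, rep.int(i, m))
        to <- c(to, targets)
        deg[targets] <- deg[targets] + 1L
        deg[i] <- deg[i] + m
      }
      edges <- cbind(from, to)
    } else if (spec$model == "erdos-renyi") {
      g0 <- igraph::sample_gnp(n, spec$er_p)
      if (igraph::ecount(g0) == 0L) {
        oncotopo_abort("empty network: Erdős–Rényi draw produced no edges", "empty_network")
      }
      edges <- igraph::as_edgelist(g0, names = FALSE)
    } else {
      from <- 1L
      to <- 2L
      nbrs <- list(2L, 1L)
      for (i in seq.int(3L, n)) {
        anchor <- sample.int(i - 1L, 1L)
        kept <- nbrs[[anchor]][stats::runif(length(nbrs[[anchor]])) < spec$dd_retention]
        if (length(kept) == 0L) kept <- anchor
        from <- c(from, rep.int(i, length(kept)))
        to <- c(to, kept)
        nbrs[[i]] <- kept
        for (k in kept) nbrs[[k]] <- c(nbrs[[k]], i)
      }
      edges <- cbind(from, to)
    }
    syms <- synthetic_symbols(n)
    as_interaction_network(syms[edges[, 1]], syms[edges[, 2]],
      extra_nodes = syms, quiet = TRUE
    )
  })
}

#' Plant gene sets with controllable hub bias
#'
#' Members are sampled without replacement with probability proportional to
#' `degree^alpha`: `alpha = 0` is uniform, larger values concentrate the set
#' on hubs. Sets are made disjoint by sequential removal unless
#' `overlap_fraction > 0`, in which case that fraction of each later set is
#' drawn from already-planted genes.
#'
#' @param network an `igraph` network.
#' @param set_specs tibble with `name`, `size`, `alpha` columns.
#' @param seed integer seed.
#' @param overlap_fraction see [synthetic_spec()].
#' @return named list of symbol vectors.
#' @export
plant_gene_sets <- function(network, set_specs, seed = 1L, overlap_fraction = 0) {
  stopifnot(igraph::is_igraph(network))
  set_specs <- as_tibble(set_specs)
  nodes <- igraph::V(network)$name
  deg <- as.numeric(igraph::degree(network))
  if (sum(set_specs$size) > length(nodes)) {
    oncotopo_abort("set sizes exceed the number of network nodes", "spec")
  }
  with_seed(seed, {
    available <- rep(TRUE, length(nodes))
    planted <- character(0)
    out <- list()
    for (i in seq_len(nrow(set_specs))) {
      size <- set_specs$size[[i]]
      alpha <- set_specs$alpha[[i]]
      n_shared <- if (i > 1L) min(round(overlap_fraction * size), length(planted)) else 0L
      shared <- if (n_shared > 0L) sample(planted, n_shared) else character(0)
      pool <- which(available)
      wgt <- if (alpha == 0) rep(1, length(pool)) else deg[pool]^alpha
      if (sum(wgt > 0) < size - n_shared) {
        oncotopo_abort(sprintf(
          "cannot plant set '%s': only %d nodes with positive sampling weight",
          set_specs$name[[i]], sum(wgt > 0)
        ), "spec")
      }
      fresh_idx <- pool[sample.int(length(pool), size - n_shared, prob = wgt)]
      members <- sort(c(nodes[fresh_idx], shared))
      available[fresh_idx] <- FALSE
      planted <- union(planted, members)
      out[[set_specs$name[[i]]]] <- members
    }
    out
  })
}

#' Simulate a somatic mutation table
#'
#' Independent Bernoulli draw per (sample, gene): the success probability is
#' the gene's set rate (background rate for unassigned genes) times the
#' sample's tumor-type multiplier, clamped to \[0, 1\] with a warning. Genes
#' in several sets take the maximum of their set rates. Emits MAF-like
#' records plus the full sample manifest, so mutation-free samples keep their
#' place in frequency denominators.
#'
#' @param sets named list of symbol vectors (typically from
#'   [plant_gene_sets()]).
#' @param spec a [synthetic_spec()] carrying rates, tumor types and the
#'   background rate.
#' @param genes full gene universe; defaults to the union of the sets.
#'   Unassigned genes mutate at `spec$background_rate`.
#' @param seed integer seed (defaults to `spec$seed`).
#' @return a `mutation_table`.
#' @export
simulate_mutations <- function(sets, spec, genes = NULL, seed = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  seed <- seed %||% spec$seed
  rates <- setNames(spec$set_specs$rate, spec$set_specs$name)
  missing_rate <- setdiff(names(sets), names(rates))
  if (length(missing_rate) > 0L) {
    oncotopo_abort(sprintf("no rate for set(s): %s", paste(missing_rate, collapse = ", ")), "spec")
  }
  genes <- genes %||% sort(unique(unlist(sets, use.names = FALSE)))
  gene_rate <- setNames(rep(spec$background_rate, length(genes)), genes)
  for (nm in names(sets)) {
    members <- intersect(sets[[nm]], genes)
    gene_rate[members] <- pmax(gene_rate[members], rates[[nm]])
  }

  tt <- spec$tumor_types
  samples <- tibble(
    sample_id = sprintf("S%05d", seq_len(sum(tt$n_samples))),
    tumor_type = rep(tt$tumor_type, tt$n_samples),
    multiplier = rep(tt$multiplier, tt$n_samples)
  )

  p <- outer(samples$multiplier, unname(gene_rate))
  if (any(p > 1)) {
    rlang::warn("simulate_mutations: some rate x multiplier products exceeded 1 and were clamped")
    p <- pmin(p, 1)
  }
  with_seed(seed, {
    hits <- which(stats::runif(length(p)) < p)
    row_i <- ((hits - 1L) %% nrow(samples)) + 1L
    col_j <- ((hits - 1L) %/% nrow(samples)) + 1L
    classes <- c(
      "Missense_Mutation", "Nonsense_Mutation", "Frame_Shift_Del",
      "Splice_Site", "Silent"
    )
    records <- tibble(
      sample_id = samples$sample_id[row_i],
      gene = genes[col_j],
      tumor_type = samples$tumor_type[row_i],
      variant_class = sample(classes, length(hits),
        replace = TRUE,
        prob = c(0.6, 0.1, 0.1, 0.1, 0.1)
      )
    )
    vocab <- if (all(tt$tumor_type %in% tumor_type_vocabulary())) tumor_type_vocabulary() else NULL
    mutation_table(records, samples[, c("sample_id", "tumor_type")], vocabulary = vocab)
  })
}

#' Generate the full synthetic study bundle
#'
#' @param spec a [synthetic_spec()].
#' @return list with `network`, `sets` (named symbol lists) and `table`
#'   (a `mutation_table`), all deterministic in `spec$seed`.
#' @export
synthetic_study <- function(spec = synthetic_spec()) {
  network <- generate_network(spec)
  sets <- plant_gene_sets(network, spec$set_specs,
    seed = spec$seed + 1L,
    overlap_fraction = spec$overlap_fraction
  )
  table <- simulate_mutations(sets, spec,
    genes = igraph::V(network)$name,
    seed = spec$seed + 2L
  )
  list(network = network, sets = sets, table = table, spec = spec)
}

#' Write a synthetic study to disk in the dialects the readers accept
#'
#' Writes `network.tsv` (edge list), `sets.gmt`, `mutations.tsv` (MAF-like)
#' and `samples.tsv` (manifest) under `dir`.
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created if needed).
#' @return named vector of the written paths, invisibly.
#' @export
write_synthetic_study <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  study <- synthetic_study(spec)
  paths <- c(
    network = file.path(dir, "network.tsv"),
    sets = file.path(dir, "sets.gmt"),
    mutations = file.path(dir, "mutations.tsv"),
    manifest = file.path(dir, "samples.tsv")
  )
  write_interactions(study$network, paths[["network"]])
  write_gmt(study$sets, paths[["sets"]])
  write_mutation_table(study$table, paths[["mutations"]], manifest_path = paths[["manifest"]])
  invisible(paths)
}
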