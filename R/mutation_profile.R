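#' Variant classes conventionally treated as silent
#' @keywords internal
silent_variant_classes <- function() {
  c("Silent", "Synonymous", "3'UTR", "5'UTR", "3'Flank", "5'Flank", "Intron", "IGR", "RNA")
}

# Distinct mutated (sample, gene) pairs after optional variant-class
# filtering; a sample with several mutations in a gene counts once.
mutated_pairs <- function(table, nonsilent_only = FALSE) {
  rec <- table$records
  if (nonsilent_only) {
    rec <- dplyr::filter(rec, !.data$variant_class %in% silent_variant_classes())
  }
  dplyr::distinct(rec, .data$sample_id, .data$gene)
}

stratum_denominators <- function(table) {
  per_type <- dplyr::count(table$samples, .data$tumor_type, name = "n_samples")
  dplyr::bind_rows(
    tibble(stratum = "ALL", n_samples = nrow(table$samples)),
    tibble(stratum = per_type$tumor_type, n_samples = per_type$n_samples)
  )
}

#' Percent of samples mutated in one gene
#'
#' The frequency is `100 * (samples in the stratum with at least one
#' qualifying record for the gene) / (samples in the stratum)`; the
#' denominator comes from the sample manifest, so mutation-free samples
#' count.
#'
#' @param table a `mutation_table`.
#' @param gene gene symbol.
#' @param tumor_type a tumor-type label present in the manifest, or `"ALL"`.
#' @param nonsilent_only count only non-silent variant classes.
#' @return frequency in percent (0-100).
#' @export
gene_mutation_frequency <- function(table, gene, tumor_type = "ALL", nonsilent_only = FALSE) {
  stopifnot(inherits(table, "mutation_table"), length(gene) == 1L)
  if (tumor_type == "ALL") {
    denom <- nrow(table$samples)
    stratum_samples <- table$samples$sample_id
  } else {
    if (!tumor_type %in% table$samples$tumor_type) {
      oncotopo_abort(sprintf("unknown tumor_type '%s' (not in the sample manifest)", tumor_type), "stratum")
    }
    stratum_samples <- table$samples$sample_id[table$samples$tumor_type == tumor_type]
    denom <- length(stratum_samples)
  }
  if (denom == 0L) {
    oncotopo_abort(sprintf("zero samples in stratum '%s'", tumor_type), "stratum")
  }
  pairs <- mutated_pairs(table, nonsilent_only)
  hit <- sum(pairs$gene == gene & pairs$sample_id %in% stratum_samples)
  100 * hit / denom
}

#' Per-gene and per-set mutation-frequency profile
#'
#' Computes the percent of samples mutated for every gene of every mapped
#' catalog set, overall (`"ALL"`) and per tumor type, and summarizes each set
#' by the arithmetic mean of its member-gene frequencies. Genes of a set with
#' no recorded mutation enter their set's distribution as 0 — they are real
#' members. A gene in several sets contributes to each of them.
#'
#' @param table a `mutation_table`.
#' @param catalog a `gene_catalog`.
#' @param nonsilent_only count only non-silent variant classes.
#' @return a `mutation_profile` with tibbles `per_gene` (gene, stratum,
#'   frequency), `per_set` (set, stratum, n_genes, mean_frequency),
#'   `denominators`, and `membership` (set, gene).
#' @export
set_frequency_profile <- function(table, catalog, nonsilent_only = FALSE) {
  stopifnot(inherits(table, "mutation_table"), inherits(catalog, "gene_catalog"))
  membership <- tidy(catalog)
  genes <- unique(membership$gene)
  no_data <- names(catalog$mapped)[vapply(
    catalog$mapped, function(g) !any(g %in% table$records$gene), TRUE
  )]
  if (length(no_data) > 0L) {
    rlang::warn(sprintf(
      "set(s) with zero genes carrying mutation records: %s",
      paste(no_data, collapse = ", ")
    ))
  }

  pairs <- dplyr::inner_join(
    mutated_pairs(table, nonsilent_only),
    table$samples,
    by = "sample_id"
  )
  pairs <- dplyr::filter(pairs, .data$gene %in% genes)
  denoms <- stratum_denominators(table)

  by_type <- dplyr::count(pairs, .data$gene, stratum = .data$tumor_type, name = "n_mutated")
  overall <- dplyr::count(pairs, .data$gene, name = "n_mutated")
  overall$stratum <- "ALL"
  counts <- dplyr::bind_rows(by_type, overall)

  grid <- tidyr::expand_grid(gene = genes, stratum = denoms$stratum)
  per_gene <- dplyr::left_join(grid, counts, by = c("gene", "stratum"))
  per_gene <- dplyr::left_join(per_gene, denoms, by = "stratum")
  per_gene <- dplyr::mutate(
    per_gene,
    frequency = 100 * dplyr::coalesce(.data$n_mutated, 0L) / .data$n_samples
  )
  per_gene <- dplyr::select(per_gene, "gene", "stratum", "frequency")

  per_set <- dplyr::inner_join(membership, per_gene, by = "gene",
                               relationship = "many-to-many")
  per_set <- dplyr::summarise(
    per_set,
    n_genes = dplyr::n(),
    mean_frequency = mean(.data$frequency),
    .by = c("set", "stratum")
  )

  structure(
    list(
      per_gene = per_gene,
      per_set = per_set,
      denominators = denoms,
      membership = membership,
      nonsilent_only = nonsilent_only
    ),
    class = "mutation_profile"
  )
}

#' @export
print.mutation_profile <- function(x, ...) {
  cat(sprintf(
    "<mutation_profile> %d genes x %d strata; sets: %s\n",
    dplyr::n_distinct(x$per_gene$gene),
    dplyr::n_distinct(x$per_gene$stratum),
    paste(unique(x$membership$set), collapse = ", ")
  ))
  print(dplyr::filter(x$per_set, .data$stratum == "ALL"))
  invisible(x)
}

#' Per-gene frequencies of a set in a stratum
#'
#' @param profile a `mutation_profile`.
#' @param set set name.
#' @param stratum tumor-type label or `"ALL"`.
#' @return named numeric vector of member-gene frequencies (percent).
#' @export
set_frequencies <- function(profile, set, stratum = "ALL") {
  stopifnot(inherits(profile, "mutation_profile"))
  members <- profile$membership$gene[profile$membership$set == set]
  if (length(members) == 0L) {
    oncotopo_abort(sprintf("unknown set '%s'", set), "set")
  }
  sub <- dplyr::filter(profile$per_gene, .data$stratum == !!stratum, .data$gene %in% members)
  setNames(sub$frequency, sub$gene)
}

#' @method tidy mutation_profile
#' @export
tidy.mutation_profile <- function(x, ...) x$per_gene

#' @method glance mutation_profile
#' @export
glance.mutation_profile <- function(x, ...) {
  all_means <- dplyr::filter(x$per_set, .data$stratum == "ALL")
  tidyr::pivot_wider(
    dplyr::select(all_means, "set", "mean_frequency"),
    names_from = "set", values_from = "mean_frequency", names_prefix = "mean_"
  )
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' The statistic is the supremum over all sample points of the absolute
#' difference of the two empirical distribution functions; the two-sided
#' p-value is the asymptotic Kolmogorov approximation with effective sample
#' size `n1 * n2 / (n1 + n2)` (ties make it approximate, as usual for
#' frequency data with many zeros).
#'
#' @param x,y numeric vectors (at least one observation each).
#' @return a `ks_result` with `statistic`, `p_value`, `n1`, `n2`, `ties`.
#' @export
ks_two_sample <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L) {
    oncotopo_abort("ks_two_sample needs at least one observation per sample", "ks")
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  ht <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  structure(
    list(
      statistic = unname(ht$statistic),
      p_value = unname(ht$p.value),
      n1 = length(x),
      n2 = length(y),
      ties = ties
    ),
    class = "ks_result"
  )
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("<ks_result> D = %.4f, p = %.3g (n1 = %d, n2 = %d%s)\n",
              x$statistic, x$p_value, x$n1, x$n2,
              if (x$ties) ", ties" else ""))
  invisible(x)
}

#' @method tidy ks_result
#' @export
tidy.ks_result <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value, n1 = x$n1, n2 = x$n2, ties = x$ties)
}

#' Pairwise K-S comparison of set frequency distributions
#'
#' @param profile a `mutation_profile`.
#' @param stratum tumor-type label or `"ALL"`.
#' @param sets which sets to compare (default: all in the profile).
#' @return tibble over all ordered set pairs with columns `set_a`, `set_b`,
#'   `statistic`, `p_value`, `n1`, `n2`, `untestable`. The implied matrix is
#'   symmetric with a zero diagonal; pairs where a set has an empty frequency
#'   list are flagged untestable rather than erroring.
#' @export
compare_sets <- function(profile, stratum = "ALL", sets = NULL) {
  stopifnot(inherits(profile, "mutation_profile"))
  sets <- sets %||% unique(profile$membership$set)
  values <- lapply(setNames(sets, sets), function(s) {
    unname(set_frequencies(profile, s, stratum))
  })
  ks_pair_table(values)
}

# Shared worker: full ordered-pair K-S grid over named value lists.
ks_pair_table <- function(values) {
  sets <- names(values)
  if (sum(lengths(values) > 0L) < 2L) {
    oncotopo_abort("need at least two sets with nonempty value lists", "ks")
  }
  grid <- tidyr::expand_grid(set_a = sets, set_b = sets)
  rows <- purrr::pmap(grid, function(set_a, set_b) {
    x <- values[[set_a]]
    y <- values[[set_b]]
    if (length(x) == 0L || length(y) == 0L) {
      return(tibble(
        set_a = set_a, set_b = set_b, statistic = NA_real_, p_value = NA_real_,
        n1 = length(x), n2 = length(y), untestable = TRUE
      ))
    }
    r <- ks_two_sample(x, y)
    tibble(
      set_a = set_a, set_b = set_b, statistic = r$statistic, p_value = r$p_value,
      n1 = r$n1, n2 = r$n2, untestable = FALSE
    )
  })
  dplyr::bind_rows(rows)
}

#' Reshape a pairwise K-S table into a matrix
#'
#' @param pairs tibble from [compare_sets()] (or the K-S tables inside a
#'   topology profile).
#' @param value `"statistic"` or `"p_value"`.
#' @return a named square matrix.
#' @export
ks_matrix <- function(pairs, value = c("statistic", "p_value")) {
  value <- match.arg(value)
  wide <- tidyr::pivot_wider(
    dplyr::select(pairs, "set_a", "set_b", dplyr::all_of(value)),
    names_from = "set_b", values_from = dplyr::all_of(value)
  )
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$set_a
  m[rownames(m), rownames(m), drop = FALSE]
}
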