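#' Minimum shortest-path distance from every node to a source set
#'
#' Multi-source breadth-first search: each node's value is the minimum
#' edge-count distance over members of the source set; source members are at
#' distance 0 and nodes in components without a source member are `Inf`
#' (unreachable).
#'
#' @param network an `igraph` network.
#' @param source symbol set (only members present in the network are used).
#' @return named numeric vector over all nodes (non-negative integers, or
#'   `Inf` for unreachable).
#' @export
min_distance_to_set <- function(network, source) {
  stopifnot(igraph::is_igraph(network))
  src <- intersect(unique(source), igraph::V(network)$name)
  if (length(src) == 0L) {
    oncotopo_abort("source set maps to zero network nodes", "proximity")
  }
  d <- igraph::distances(network, v = src)
  out <- apply(d, 2, min)
  setNames(as.numeric(out), colnames(d))
}

#' Distance distribution of catalog sets around a source set
#'
#' For each catalog set, the proportion of its mapped members found at each
#' shortest-path distance from the source set. Distances beyond `max_distance`
#' are pooled into a `">max"` bin and members with no path to the source get
#' an `"unreachable"` bin, so every set's proportions sum to 1. Set members
#' that are themselves in the source occupy bin 0.
#'
#' @param distances named distance vector from [min_distance_to_set()].
#' @param catalog a `gene_catalog` over the same network.
#' @param max_distance largest individually reported distance (default 8).
#' @return a `distance_profile` with tibbles `per_set` (set, distance,
#'   n, proportion) and `per_node`.
#' @export
proximity_distribution <- function(distances, catalog, max_distance = 8L) {
  stopifnot(inherits(catalog, "gene_catalog"))
  missing_nodes <- setdiff(catalog$universe, names(distances))
  if (length(missing_nodes) > 0L) {
    oncotopo_abort("distances were not computed on the catalog's network", "proximity")
  }
  membership <- tidy(catalog)
  per_node <- tibble(node = names(distances), distance = unname(distances))
  bins <- dplyr::mutate(
    dplyr::inner_join(membership, per_node, by = c(gene = "node")),
    bin = dplyr::case_when(
      is.infinite(.data$distance) ~ "unreachable",
      .data$distance > max_distance ~ paste0(">", max_distance),
      TRUE ~ as.character(as.integer(pmin(.data$distance, max_distance)))
    )
  )
  per_set <- dplyr::count(bins, .data$set, .data$bin, name = "n")
  per_set <- dplyr::mutate(per_set, proportion = .data$n / sum(.data$n), .by = "set")
  bin_levels <- c(as.character(0:max_distance), paste0(">", max_distance), "unreachable")
  per_set <- dplyr::arrange(
    dplyr::mutate(per_set, bin = factor(.data$bin, levels = bin_levels)),
    .data$set, .data$bin
  )
  per_set <- dplyr::rename(per_set, distance = "bin")
  structure(
    list(per_set = per_set, per_node = per_node, max_distance = max_distance),
    class = "distance_profile"
  )
}

#' @export
print.distance_profile <- function(x, ...) {
  cat(sprintf("<distance_profile> %d sets, distances reported up to %d\n",
              dplyr::n_distinct(x$per_set$set), x$max_distance))
  print(tidyr::pivot_wider(x$per_set, id_cols = "set", names_from = "distance",
                           values_from = "proportion", values_fill = 0))
  invisible(x)
}

#' @method tidy distance_profile
#' @export
tidy.distance_profile <- function(x, ...) x$per_set

#' Fraction of a query set directly interacting with a source set
#'
#' A query member counts when it has at least one network neighbor inside the
#' source set. Membership in the source set does not by itself count: a
#' shared member needs a source neighbor like any other node, so the
#' statistic is independent of set overlap.
#'
#' @param network an `igraph` network.
#' @param query symbol set being scored.
#' @param source symbol set interacted with.
#' @return proportion in `[0, 1]` of mapped query members with a source
#'   neighbor.
#' @export
direct_interaction_fraction <- function(network, query, source) {
  stopifnot(igraph::is_igraph(network))
  nodes <- igraph::V(network)$name
  q <- intersect(unique(query), nodes)
  s <- intersect(unique(source), nodes)
  if (length(q) == 0L) {
    oncotopo_abort("query set maps to zero network nodes", "proximity")
  }
  if (length(s) == 0L) {
    oncotopo_abort("source set maps to zero network nodes", "proximity")
  }
  has_source_neighbor <- vapply(q, function(v) {
    nb <- names(igraph::neighbors(network, v))
    any(nb %in% s)
  }, TRUE)
  mean(has_source_neighbor)
}

#' Direct-interaction summary of catalog sets against a source set
#'
#' @param network an `igraph` network.
#' @param catalog a `gene_catalog`.
#' @param source symbol set (e.g. the mapped drug-target set).
#' @return tibble with, per set, the fraction of members with a source
#'   neighbor (`direct_fraction`) and the fraction within distance 1-2
#'   (`within_2_fraction`, distance-0 overlap members included).
#' @export
direct_interaction_summary <- function(network, catalog, source) {
  stopifnot(inherits(catalog, "gene_catalog"))
  d <- min_distance_to_set(network, source)
  membership <- tidy(catalog)
  dplyr::summarise(
    dplyr::mutate(membership, distance = d[.data$gene]),
    n = dplyr::n(),
    direct_fraction = direct_interaction_fraction(network, .data$gene, source),
    within_2_fraction = mean(.data$distance >= 1 & .data$distance <= 2),
    .by = "set"
  )
}
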