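#' Node degree
#'
#' Number of distinct neighbors (the network is simple, so this is the edge
#' count at the node).
#'
#' @param network an `igraph` network.
#' @param node a node name (or vector of names).
#' @return integer degree(s).
#' @export
node_degree <- function(network, node) {
  check_nodes(network, node)
  as.integer(igraph::degree(network, v = node))
}

check_nodes <- function(network, node) {
  missing_nodes <- setdiff(node, igraph::V(network)$name)
  if (length(missing_nodes) > 0L) {
    oncotopo_abort(sprintf(
      "unknown node(s): %s", paste(head(missing_nodes, 5L), collapse = ", ")
    ), "node")
  }
  invisible(TRUE)
}

#' Betweenness centrality for every node
#'
#' Unnormalized shortest-path betweenness (Brandes pair-dependency
#' accumulation): for each unordered pair of other nodes, a node receives the
#' fraction of their shortest paths passing through it; endpoints are
#' excluded and each unordered pair is counted once. Reported raw, not
#' rescaled, because set-level comparisons use the raw counts; set
#' `normalized = TRUE` to divide by `(n-1)(n-2)/2`.
#'
#' @param network an `igraph` network.
#' @param normalized rescale to `[0, 1]`.
#' @return named numeric vector over all nodes.
#' @export
betweenness_all <- function(network, normalized = FALSE) {
  stopifnot(igraph::is_igraph(network))
  if (igraph::vcount(network) == 0L) {
    oncotopo_abort("empty network", "empty_network")
  }
  b <- igraph::betweenness(network, directed = FALSE, normalized = normalized)
  setNames(as.numeric(b), igraph::V(network)$name)
}

#' Local clustering coefficient
#'
#' Edges observed among a node's neighbors divided by the `k(k-1)/2` possible
#' ones. Nodes with fewer than two neighbors have no possible neighbor pairs
#' and are assigned 0 by convention (set `exclude_low_degree = TRUE` to get
#' `NA` instead, which drops them from set averages).
#'
#' @param network an `igraph` network.
#' @param node node name (or vector of names).
#' @param exclude_low_degree return `NA` rather than 0 for degree < 2.
#' @return numeric in `[0, 1]` (or `NA`).
#' @export
clustering_coefficient <- function(network, node, exclude_low_degree = FALSE) {
  check_nodes(network, node)
  cc <- suppressWarnings(
    igraph::transitivity(network, type = "local", vids = node, isolates = "NaN")
  )
  cc[is.nan(cc)] <- if (exclude_low_degree) NA_real_ else 0
  unname(cc)
}

#' Mean shortest-path distance from a node
#'
#' Breadth-first (edge-count) distances to every other reachable node —
#' neighbors are at distance 1 — averaged arithmetically. Nodes outside the
#' node's component are excluded from the mean; an isolated node has no
#' reachable partner and gets `NA`.
#'
#' @param network an `igraph` network.
#' @param node a single node name.
#' @return positive mean distance, or `NA` for an isolated node.
#' @export
mean_shortest_path <- function(network, node) {
  check_nodes(network, node)
  stopifnot(length(node) == 1L)
  d <- igraph::distances(network, v = node)[1, ]
  d <- d[names(d) != node]
  d <- d[is.finite(d)]
  if (length(d) == 0L) {
    return(NA_real_)
  }
  mean(d)
}

mean_spd_all <- function(network) {
  d <- igraph::distances(network)
  diag(d) <- NA
  d[!is.finite(d)] <- NA
  out <- rowMeans(d, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  setNames(out, igraph::V(network)$name)
}

#' Topology profile of catalog sets on a network
#'
#' Computes degree, betweenness, local clustering coefficient and mean
#' shortest-path distance for every node, assembles per-set metric
#' distributions over the mapped members, and runs pairwise two-sample K-S
#' tests per metric. All metrics are computed within components; no
#' largest-component restriction is applied unless requested.
#'
#' @param network an `igraph` network.
#' @param catalog a `gene_catalog` built on the same network.
#' @param exclude_low_degree_clustering drop degree < 2 nodes from clustering
#'   averages instead of counting them as 0.
#' @param largest_component restrict all metrics to the largest connected
#'   component.
#' @param normalized_betweenness rescale betweenness to `[0, 1]`.
#' @return a `topology_profile` with tibbles `per_node` (node, degree,
#'   betweenness, clustering, mean_spd), `per_set` (set, metric, n, mean) and
#'   `ks` (metric, set_a, set_b, statistic, p_value, ...).
#' @export
topology_profile <- function(network, catalog,
                             exclude_low_degree_clustering = FALSE,
                             largest_component = FALSE,
                             normalized_betweenness = FALSE) {
  stopifnot(igraph::is_igraph(network), inherits(catalog, "gene_catalog"))
  if (largest_component) {
    comp <- igraph::components(network)
    keep <- igraph::V(network)$name[comp$membership == which.max(comp$csize)]
    network <- igraph::induced_subgraph(network, keep)
  }
  nodes <- igraph::V(network)$name
  per_node <- tibble(
    node = nodes,
    degree = as.integer(igraph::degree(network)),
    betweenness = unname(betweenness_all(network, normalized = normalized_betweenness)),
    clustering = clustering_coefficient(network, nodes,
      exclude_low_degree = exclude_low_degree_clustering
    ),
    mean_spd = unname(mean_spd_all(network))
  )

  membership <- dplyr::filter(tidy(catalog), .data$gene %in% nodes)
  long <- tidyr::pivot_longer(
    dplyr::inner_join(membership, per_node, by = c(gene = "node")),
    cols = c("degree", "betweenness", "clustering", "mean_spd"),
    names_to = "metric", values_to = "value"
  )
  per_set <- dplyr::summarise(
    long,
    n = sum(!is.na(.data$value)),
    mean = mean(.data$value, na.rm = TRUE),
    .by = c("set", "metric")
  )

  sets <- unique(membership$set)
  ks <- dplyr::bind_rows(lapply(
    c("degree", "betweenness", "clustering", "mean_spd"),
    function(m) {
      vals <- lapply(setNames(sets, sets), function(s) {
        v <- long$value[long$set == s & long$metric == m]
        v[!is.na(v)]
      })
      out <- ks_pair_table(vals)
      out$metric <- m
      dplyr::relocate(out, "metric")
    }
  ))

  structure(
    list(per_node = per_node, per_set = per_set, ks = ks, membership = membership),
    class = "topology_profile"
  )
}

#' @export
print.topology_profile <- function(x, ...) {
  cat(sprintf("<topology_profile> %d nodes, %d sets\n",
              nrow(x$per_node), dplyr::n_distinct(x$membership$set)))
  print(tidyr::pivot_wider(x$per_set, id_cols = "set", names_from = "metric",
                           values_from = "mean"))
  invisible(x)
}

#' @method tidy topology_profile
#' @export
tidy.topology_profile <- function(x, ...) x$per_node

#' @method glance topology_profile
#' @export
glance.topology_profile <- function(x, ...) {
  tidyr::pivot_wider(
    dplyr::select(x$per_set, "set", "metric", "mean"),
    names_from = c("metric", "set"), values_from = "mean", names_sep = "_"
  )
}

#' Per-set metric values of a topology profile
#'
#' @param profile a `topology_profile`.
#' @param set set name.
#' @param metric one of `"degree"`, `"betweenness"`, `"clustering"`,
#'   `"mean_spd"`.
#' @return named numeric vector over the set's mapped members.
#' @export
set_metric_values <- function(profile, set,
                              metric = c("degree", "betweenness", "clustering", "mean_spd")) {
  metric <- match.arg(metric)
  stopifnot(inherits(profile, "topology_profile"))
  members <- profile$membership$gene[profile$membership$set == set]
  if (length(members) == 0L) {
    oncotopo_abort(sprintf("unknown set '%s'", set), "set")
  }
  sub <- profile$per_node[match(members, profile$per_node$node), ]
  setNames(as.numeric(sub[[metric]]), sub$node)
}
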