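set_palette <- function() {
  c(
    TSG = "#d62728", OCG = "#1f77b4", Target = "#9467bd",
    Essential = "#2ca02c", Other = "#7f7f7f"
  )
}

apply_set_palette <- function(p, sets) {
  pal <- set_palette()
  if (all(sets %in% names(pal))) {
    p <- p + ggplot2::scale_fill_manual(values = pal)
  }
  p
}

#' Plot set-level mutation frequencies
#'
#' Bars of mean per-gene mutation frequency per set, optionally faceted by
#' tumor type.
#'
#' @param object a `mutation_profile`.
#' @param strata which strata to show; default `"ALL"`. Use
#'   `strata = NULL` for all tumor types.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot mutation_profile
#' @export
autoplot.mutation_profile <- function(object, strata = "ALL", ...) {
  d <- object$per_set
  if (!is.null(strata)) d <- dplyr::filter(d, .data$stratum %in% strata)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$set, y = .data$mean_frequency, fill = .data$set)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$stratum)) +
    ggplot2::labs(x = NULL, y = "samples mutated (%)") +
    ggplot2::theme_minimal()
  apply_set_palette(p, unique(d$set))
}

#' @rdname autoplot.mutation_profile
#' @param profile a `mutation_profile`.
#' @export
plot_mutation_frequency <- function(profile, strata = "ALL") {
  autoplot.mutation_profile(profile, strata = strata)
}

#' Plot per-set topology metric distributions
#'
#' @param object a `topology_profile`.
#' @param metric which metric to show.
#' @param log_scale log10 y axis (useful for degree and betweenness).
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot topology_profile
#' @export
autoplot.topology_profile <- function(object,
                                      metric = c("degree", "betweenness", "clustering", "mean_spd"),
                                      log_scale = metric %in% c("degree", "betweenness"),
                                      ...) {
  metric <- match.arg(metric)
  long <- dplyr::inner_join(object$membership, object$per_node, by = c(gene = "node"))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$set, y = .data[[metric]], fill = .data$set)) +
    ggplot2::geom_boxplot(show.legend = FALSE, outlier.size = 0.4) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal()
  if (isTRUE(log_scale)) p <- p + ggplot2::scale_y_log10()
  apply_set_palette(p, unique(long$set))
}

#' @rdname autoplot.topology_profile
#' @param profile a `topology_profile`.
#' @export
plot_topology_metric <- function(profile, metric = "degree") {
  autoplot.topology_profile(profile, metric = metric)
}

#' Plot distance-to-source distributions
#'
#' Per-set proportions at each shortest-path distance from the source set.
#'
#' @param object a `distance_profile`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot distance_profile
#' @export
autoplot.distance_profile <- function(object, ...) {
  p <- ggplot2::ggplot(
    object$per_set,
    ggplot2::aes(x = .data$distance, y = .data$proportion, fill = .data$set)
  ) +
    ggplot2::geom_col(position = ggplot2::position_dodge2(preserve = "single")) +
    ggplot2::labs(x = "shortest-path distance to source set", y = "proportion of set") +
    ggplot2::theme_minimal()
  pal <- set_palette()
  if (all(unique(object$per_set$set) %in% names(pal))) {
    p <- p + ggplot2::scale_fill_manual(values = pal, name = NULL)
  }
  p
}

#' @rdname autoplot.distance_profile
#' @param profile a `distance_profile`.
#' @export
plot_proximity <- function(profile) autoplot.distance_profile(profile)

#' Plot a Steiner subnetwork
#'
#' Base-graphics network drawing with the conventional coloring: terminal set
#' A red, terminal set B blue, linkers green; node size scales with attached
#' mutation frequency when available.
#'
#' @param x a `steiner_subnetwork`.
#' @param ... forwarded to [igraph::plot.igraph()].
#' @export
plot.steiner_subnetwork <- function(x, ...) {
  g <- subnetwork_graph(x)
  role <- igraph::V(g)$role
  col <- dplyr::case_when(
    role == "terminal-A" ~ "#d62728",
    role == "terminal-B" ~ "#1f77b4",
    role == "terminal-A+B" ~ "#9467bd",
    TRUE ~ "#2ca02c"
  )
  mf <- igraph::V(g)$mutation_frequency
  size <- if (all(is.na(mf))) 6 else 4 + 10 * sqrt(pmax(mf, 0) / max(mf, 1, na.rm = TRUE))
  ecol <- dplyr::case_when(
    igraph::E(g)$category == "A-A" ~ "#d62728",
    igraph::E(g)$category == "B-B" ~ "#1f77b4",
    igraph::E(g)$category == "A-B" ~ "#006400",
    TRUE ~ "grey60"
  )
  igraph::plot.igraph(g,
    vertex.color = col, vertex.size = size, vertex.label.cex = 0.6,
    edge.color = ecol, ...
  )
  invisible(x)
}
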