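#' Build a node-weighted Steiner instance
#'
#' Terminals are the nodes of interest (here: the union of two terminal
#' sets); every other node is a potential linker whose weight is the price of
#' including it. Terminals always cost 0. With the default unit weights the
#' Klein-Ravi objective minimizes the number of linkers.
#'
#' @param network an `igraph` network.
#' @param terminals symbol set; members absent from the network are logged
#'   and dropped.
#' @param node_weights optional named non-negative weights for non-terminal
#'   nodes (default 1); terminal weights are forced to 0.
#' @param quiet suppress the unmapped-terminal message.
#' @return a `steiner_instance`.
#' @export
steiner_instance <- function(network, terminals, node_weights = NULL, quiet = FALSE) {
  stopifnot(igraph::is_igraph(network))
  nodes <- igraph::V(network)$name
  terminals <- unique(stringr::str_trim(terminals))
  unmapped <- setdiff(terminals, nodes)
  mapped <- intersect(terminals, nodes)
  if (length(mapped) == 0L) {
    oncotopo_abort("no terminal maps into the network", "steiner")
  }
  if (length(unmapped) > 0L && !quiet) {
    rlang::inform(sprintf(
      "steiner_instance: %d terminal(s) not in the network (%s)",
      length(unmapped), paste(head(unmapped, 5L), collapse = ", ")
    ))
  }
  w <- setNames(rep(1, length(nodes)), nodes)
  if (!is.null(node_weights)) {
    if (is.null(names(node_weights))) {
      oncotopo_abort("node_weights must be a named vector", "steiner")
    }
    if (any(node_weights < 0, na.rm = TRUE)) {
      oncotopo_abort("node weights must be non-negative", "steiner")
    }
    w[names(node_weights)] <- node_weights
  }
  w[mapped] <- 0
  structure(
    list(network = network, terminals = mapped, unmapped = unmapped, weights = w),
    class = "steiner_instance"
  )
}

#' Node-weighted shortest path from a node to a target region
#'
#' Dijkstra relaxation over node weights: the cost of a path is the sum of
#' weights of its nodes excluding the source and excluding any node already
#' inside the target region. Ties are broken lexicographically by node
#' symbol, so results are bit-reproducible.
#'
#' @param instance a `steiner_instance`.
#' @param source node name.
#' @param target_region character vector of region node names.
#' @return list with `cost` (`Inf` when unreachable) and `path` (node names
#'   from source to the first region node reached; `NULL` when unreachable).
#'   A source already inside the region has cost 0 and a length-1 path.
#' @export
node_weighted_shortest_path <- function(instance, source, target_region) {
  stopifnot(inherits(instance, "steiner_instance"))
  g <- instance$network
  check_nodes(g, c(source, target_region))
  if (source %in% target_region) {
    return(list(cost = 0, path = source))
  }
  w <- instance$weights
  w[target_region] <- 0
  nw_dijkstra(g, source, target_region, w)
}

# Lexicographic node-weighted Dijkstra. Costs accumulate the weight of each
# node *entered* (source excluded); `w` must already be zeroed on the region.
nw_dijkstra <- function(g, source, region, w) {
  nodes <- igraph::V(g)$name
  n <- length(nodes)
  idx <- setNames(seq_len(n), nodes)
  adj <- igraph::adjacent_vertices(g, v = nodes)
  region_mask <- nodes %in% region

  dist <- rep(Inf, n)
  prev <- rep(NA_integer_, n)
  done <- rep(FALSE, n)
  dist[idx[[source]]] <- 0

  repeat {
    open <- which(!done & is.finite(dist))
    if (length(open) == 0L) {
      return(list(cost = Inf, path = NULL))
    }
    # pop: smallest distance, ties by node symbol
    cand <- open[dist[open] == min(dist[open])]
    u <- cand[order(nodes[cand])][[1]]
    if (region_mask[[u]]) {
      path <- u
      while (!is.na(prev[[path[[1]]]])) path <- c(prev[[path[[1]]]], path)
      return(list(cost = dist[[u]], path = nodes[path]))
    }
    done[[u]] <- TRUE
    for (v in as.integer(adj[[u]])) {
      if (done[[v]]) next
      nd <- dist[[u]] + w[[v]]
      better <- nd < dist[[v]] ||
        (nd == dist[[v]] && !is.na(prev[[v]]) && nodes[[u]] < nodes[[prev[[v]]]])
      if (better) {
        dist[[v]] <- nd
        prev[[v]] <- u
      }
    }
  }
}

# Cost from every node v to a tree: min over region members of the
# node-weighted path cost excluding v itself and region nodes. Computed with
# one Dijkstra from a virtual super-source using arc weights w(tail), so the
# terminal-side weights never enter.
kr_costs_to_tree <- function(network, tree_nodes, w) {
  nodes <- igraph::V(network)$name
  el <- igraph::as_edgelist(network, names = TRUE)
  tails <- c(el[, 1], el[, 2], rep(".kr.super.", length(tree_nodes)))
  heads <- c(el[, 2], el[, 1], tree_nodes)
  w2 <- c(w, ".kr.super." = 0)
  w2[tree_nodes] <- 0
  gd <- igraph::graph_from_data_frame(
    data.frame(from = tails, to = heads),
    directed = TRUE,
    vertices = c(nodes, ".kr.super.")
  )
  arcw <- unname(w2[tails])
  d <- igraph::distances(gd, v = ".kr.super.", to = nodes, mode = "out", weights = arcw)
  setNames(as.numeric(d[1, ]), nodes)
}

# Merge trees that touch in the induced subgraph on current tree nodes
# (closure of all zero-cost spider merges; order-independent).
kr_collapse <- function(network, trees) {
  all_nodes <- unique(unlist(trees, use.names = FALSE))
  h <- igraph::induced_subgraph(network, all_nodes)
  comp <- igraph::components(h)$membership
  comp_of_tree <- vapply(trees, function(t) comp[[t[[1]]]], 1)
  lapply(split(trees, comp_of_tree), function(group) {
    sort(unique(unlist(group, use.names = FALSE)))
  })
}

#' Klein-Ravi node-weighted Steiner tree approximation
#'
#' Spider-merge approximation: every terminal starts as its own tree; each
#' round selects the center node `v` and the group of `k >= 2` trees
#' minimizing `(weight(v) + sum of node-weighted path costs from v to each
#' tree) / k` (for each `v`, trees are scanned in ascending path-cost order
#' and the best prefix taken), then merges those trees with `v` and its
#' connecting paths. Nodes already inside a tree cost nothing as centers or
#' path members of that tree. The loop ends with one tree per connected
#' terminal group; with disconnected terminal groups the union of trees is
#' returned with a warning. All ties (equal merge ratios, equal path costs)
#' break lexicographically by node symbol, and equal-ratio groups prefer
#' merging more trees.
#'
#' A final pruning pass removes any chosen linker whose removal leaves every
#' terminal group connected in the induced subgraph, so each surviving linker
#' is necessary for some terminal pair.
#'
#' @param instance a `steiner_instance`.
#' @param prune drop redundant linkers after the merge loop (default `TRUE`).
#' @return sorted character vector of Steiner nodes (all mapped terminals
#'   plus chosen linkers).
#' @export
klein_ravi <- function(instance, prune = TRUE) {
  stopifnot(inherits(instance, "steiner_instance"))
  g <- instance$network
  w <- instance$weights
  nodes <- igraph::V(g)$name

  trees <- kr_collapse(g, as.list(instance$terminals))
  while (length(trees) > 1L) {
    in_tree <- nodes %in% unlist(trees, use.names = FALSE)
    w_center <- ifelse(in_tree, 0, w[nodes])
    cost_mat <- do.call(rbind, lapply(trees, kr_costs_to_tree, network = g, w = w))

    best <- list(ratio = Inf, node = NA_character_, k = 0L)
    for (j in seq_along(nodes)) {
      cs <- sort(cost_mat[, j])
      cs <- cs[is.finite(cs)]
      if (length(cs) < 2L) next
      k <- 2:length(cs)
      ratios <- (w_center[[j]] + cumsum(cs)[k]) / k
      jbest <- which(ratios == min(ratios))
      jk <- k[[jbest[[length(jbest)]]]] # prefer larger k at equal ratio
      jratio <- min(ratios)
      if (jratio < best$ratio ||
        (jratio == best$ratio && jk > best$k) ||
        (jratio == best$ratio && jk == best$k && nodes[[j]] < best$node)) {
        best <- list(ratio = jratio, node = nodes[[j]], k = jk)
      }
    }
    if (!is.finite(best$ratio)) {
      rlang::warn("klein_ravi: terminals span disconnected components; returning one tree per group")
      break
    }
    v <- best$node
    j <- match(v, nodes)
    sel <- order(cost_mat[, j], vapply(trees, `[[`, "", 1L))[seq_len(best$k)]
    merged <- c(v, unlist(trees[sel], use.names = FALSE))
    for (ti in sel) {
      sp <- node_weighted_shortest_path(
        steiner_instance_raw(g, instance$terminals, w),
        v, trees[[ti]]
      )
      merged <- c(merged, sp$path)
    }
    trees <- c(trees[-sel], list(sort(unique(merged))))
    trees <- kr_collapse(g, trees)
  }

  steiner_nodes <- sort(unique(unlist(trees, use.names = FALSE)))
  if (prune) {
    steiner_nodes <- prune_linkers(g, steiner_nodes, instance$terminals, w)
  }
  steiner_nodes
}

# internal constructor skipping validation (weights already prepared)
steiner_instance_raw <- function(network, terminals, weights) {
  structure(
    list(network = network, terminals = terminals, unmapped = character(), weights = weights),
    class = "steiner_instance"
  )
}

# Drop linkers whose removal keeps every terminal group connected in the
# induced subgraph. Scanned heaviest-first (ties lexicographic) so the most
# expensive redundancies go first.
prune_linkers <- function(network, steiner_nodes, terminals, w) {
  h0 <- igraph::induced_subgraph(network, steiner_nodes)
  comp0 <- igraph::components(h0)$membership
  ref_group <- comp0[intersect(steiner_nodes, terminals)]
  groups_ok <- function(node_set) {
    h <- igraph::induced_subgraph(network, node_set)
    comp <- igraph::components(h)$membership
    term <- intersect(node_set, terminals)
    all(vapply(split(term, ref_group[term]), function(ts) {
      length(unique(comp[ts])) == 1L
    }, TRUE))
  }

  linkers <- setdiff(steiner_nodes, terminals)
  linkers <- linkers[order(-w[linkers], linkers)]
  for (l in linkers) {
    trial <- setdiff(steiner_nodes, l)
    if (groups_ok(trial)) {
      steiner_nodes <- trial
    }
  }
  sort(steiner_nodes)
}

#' Edge category from endpoint roles
#' @keywords internal
edge_category <- function(role_from, role_to) {
  dplyr::case_when(
    role_from == "linker" | role_to == "linker" ~ "linker-involving",
    role_from == "terminal-A" & role_to == "terminal-A" ~ "A-A",
    role_from == "terminal-B" & role_to == "terminal-B" ~ "B-B",
    TRUE ~ "A-B"
  )
}

new_steiner_subnetwork <- function(nodes, edges, terminal_sets = c(A = "A", B = "B")) {
  structure(
    list(nodes = as_tibble(nodes), edges = as_tibble(edges), terminal_sets = terminal_sets),
    class = "steiner_subnetwork"
  )
}

#' Induced subnetwork over a Steiner node set
#'
#' Includes every network edge with both endpoints in the Steiner node set
#' (not just the tree edges), assigns each node a role — `terminal-A`,
#' `terminal-B` or `linker` — and each edge a category (`A-A`, `B-B`, `A-B`,
#' `linker-involving`). A deterministic spanning forest of the induced
#' subgraph is marked as the tree (`in_tree`), acyclic and spanning every
#' terminal of each component.
#'
#' @param network an `igraph` network.
#' @param steiner_nodes node set from [klein_ravi()].
#' @param terminal_a,terminal_b the two terminal symbol sets.
#' @param strict error when the two terminal sets share symbols (default);
#'   permissive mode assigns shared symbols the combined role
#'   `"terminal-A+B"` (categorized as `A-B` against either terminal role).
#' @param terminal_set_names length-2 character vector naming the sets (used
#'   in printing only).
#' @return a `steiner_subnetwork` with tibbles `nodes` (node, role,
#'   mutation_frequency) and `edges` (from, to, category, in_tree).
#' @export
induced_subnetwork <- function(network, steiner_nodes, terminal_a, terminal_b,
                               strict = TRUE, terminal_set_names = c("A", "B")) {
  stopifnot(igraph::is_igraph(network))
  check_nodes(network, steiner_nodes)
  shared <- intersect(terminal_a, terminal_b)
  if (length(shared) > 0L && strict) {
    oncotopo_abort(sprintf(
      "terminal sets overlap (%s); use strict = FALSE to assign a combined role",
      paste(head(shared, 10L), collapse = ", ")
    ), "steiner")
  }
  role <- dplyr::case_when(
    steiner_nodes %in% shared ~ "terminal-A+B",
    steiner_nodes %in% terminal_a ~ "terminal-A",
    steiner_nodes %in% terminal_b ~ "terminal-B",
    TRUE ~ "linker"
  )
  nodes <- tibble(node = steiner_nodes, role = role, mutation_frequency = NA_real_)
  nodes <- dplyr::arrange(nodes, .data$node)

  h <- igraph::induced_subgraph(network, nodes$node)
  el <- igraph::as_edgelist(h)
  from <- pmin(el[, 1], el[, 2])
  to <- pmax(el[, 1], el[, 2])
  ord <- order(from, to)
  from <- from[ord]
  to <- to[ord]

  tree <- igraph::mst(h)
  tel <- igraph::as_edgelist(tree)
  tree_key <- paste(pmin(tel[, 1], tel[, 2]), pmax(tel[, 1], tel[, 2]), sep = "\r")

  role_of <- setNames(nodes$role, nodes$node)
  rf <- role_of[from]
  rt <- role_of[to]
  # combined-role endpoints realize the cross-set category with any terminal
  rf2 <- ifelse(rf == "terminal-A+B", ifelse(rt == "terminal-A", "terminal-B", "terminal-A"), rf)
  rt2 <- ifelse(rt == "terminal-A+B", ifelse(rf2 == "terminal-A", "terminal-B", "terminal-A"), rt)
  edges <- tibble(
    from = from,
    to = to,
    category = edge_category(rf2, rt2),
    in_tree = paste(from, to, sep = "\r") %in% tree_key
  )
  new_steiner_subnetwork(nodes, edges, setNames(terminal_set_names, c("A", "B")))
}

#' @export
print.steiner_subnetwork <- function(x, ...) {
  role_n <- table(x$nodes$role)
  cat(sprintf(
    "<steiner_subnetwork> %d nodes (%s), %d edges (%d in tree)\n",
    nrow(x$nodes),
    paste(sprintf("%s: %d", names(role_n), role_n), collapse = ", "),
    nrow(x$edges), sum(x$edges$in_tree, na.rm = TRUE)
  ))
  invisible(x)
}

#' Rebuild an igraph object from a Steiner subnetwork
#'
#' @param subnet a `steiner_subnetwork`.
#' @return an `igraph` graph with node attributes `role`,
#'   `mutation_frequency` and edge attributes `category`, `in_tree`.
#' @export
subnetwork_graph <- function(subnet) {
  stopifnot(inherits(subnet, "steiner_subnetwork"))
  g <- igraph::graph_from_data_frame(
    subnet$edges[, c("from", "to")],
    directed = FALSE,
    vertices = subnet$nodes[, "node"]
  )
  igraph::V(g)$role <- subnet$nodes$role[match(igraph::V(g)$name, subnet$nodes$node)]
  igraph::V(g)$mutation_frequency <-
    subnet$nodes$mutation_frequency[match(igraph::V(g)$name, subnet$nodes$node)]
  igraph::E(g)$category <- subnet$edges$category
  igraph::E(g)$in_tree <- as.integer(subnet$edges$in_tree)
  g
}

#' Edge composition of a Steiner subnetwork
#'
#' Counts induced edges per category and reports them as percents (one
#' decimal), the among-terminal total (`A-A + B-B + A-B`) and, when given a
#' subnetwork, the cross-set linkage: the fraction of A-terminals with at
#' least one B-neighbor and vice versa.
#'
#' @param x a `steiner_subnetwork`, or a named integer vector of category
#'   counts (names `A-A`, `B-B`, `A-B`, `linker-involving`) when only the
#'   counts are known.
#' @return a `composition_summary` list with `counts`, `proportions`
#'   (percent), `total_edges`, `among_terminal_count`,
#'   `among_terminal_percent` and (subnetwork input only) `cross_linkage`.
#' @export
edge_composition <- function(x) {
  categories <- c("A-A", "B-B", "A-B", "linker-involving")
  cross <- NULL
  if (inherits(x, "steiner_subnetwork")) {
    counts <- table(factor(x$edges$category, levels = categories))
    counts <- setNames(as.integer(counts), categories)
    a_nodes <- x$nodes$node[x$nodes$role %in% c("terminal-A", "terminal-A+B")]
    b_nodes <- x$nodes$node[x$nodes$role %in% c("terminal-B", "terminal-A+B")]
    touches <- function(members, others) {
      if (length(members) == 0L) {
        return(NA_real_)
      }
      hit <- vapply(members, function(v) {
        any((x$edges$from == v & x$edges$to %in% others) |
          (x$edges$to == v & x$edges$from %in% others))
      }, TRUE)
      mean(hit)
    }
    cross <- tibble(
      role = c("terminal-A", "terminal-B"),
      n = c(length(a_nodes), length(b_nodes)),
      cross_linked_fraction = c(touches(a_nodes, b_nodes), touches(b_nodes, a_nodes))
    )
  } else {
    x <- x[categories]
    x[is.na(x)] <- 0L
    counts <- setNames(as.integer(x), categories)
  }
  total <- sum(counts)
  proportions <- if (total > 0L) round(100 * counts / total, 1) else setNames(rep(0, 4L), categories)
  among <- sum(counts[c("A-A", "B-B", "A-B")])
  structure(
    list(
      counts = counts,
      proportions = proportions,
      total_edges = total,
      among_terminal_count = among,
      among_terminal_percent = if (total > 0L) round(100 * among / total, 1) else 0,
      cross_linkage = cross
    ),
    class = "composition_summary"
  )
}

#' @export
print.composition_summary <- function(x, ...) {
  cat(sprintf("<composition_summary> %d edges; among-terminal %d (%.1f%%)\n",
              x$total_edges, x$among_terminal_count, x$among_terminal_percent))
  for (nm in names(x$counts)) {
    cat(sprintf("  %-16s %5d (%5.1f%%)\n", nm, x$counts[[nm]], x$proportions[[nm]]))
  }
  invisible(x)
}

#' @method tidy composition_summary
#' @export
tidy.composition_summary <- function(x, ...) {
  tibble(
    category = names(x$counts),
    n = unname(x$counts),
    percent = unname(x$proportions)
  )
}

#' @method glance composition_summary
#' @export
glance.composition_summary <- function(x, ...) {
  tibble(
    total_edges = x$total_edges,
    among_terminal_count = x$among_terminal_count,
    among_terminal_percent = x$among_terminal_percent
  )
}

#' Annotate subnetwork nodes with overall mutation frequencies
#'
#' @param subnet a `steiner_subnetwork`.
#' @param profile a `mutation_profile` with an `"ALL"` stratum.
#' @param quiet suppress the message listing nodes without mutation data.
#' @return the subnetwork with `mutation_frequency` filled (0, logged, for
#'   genes absent from the profile); node and edge sets are untouched.
#' @export
attach_mutation_frequency <- function(subnet, profile, quiet = FALSE) {
  stopifnot(inherits(subnet, "steiner_subnetwork"), inherits(profile, "mutation_profile"))
  all_freq <- dplyr::filter(profile$per_gene, .data$stratum == "ALL")
  freq <- setNames(all_freq$frequency, all_freq$gene)
  hit <- subnet$nodes$node %in% names(freq)
  if (any(!hit) && !quiet) {
    rlang::inform(sprintf(
      "attach_mutation_frequency: %d node(s) without mutation data set to 0 (%s)",
      sum(!hit), paste(head(subnet$nodes$node[!hit], 5L), collapse = ", ")
    ))
  }
  subnet$nodes$mutation_frequency <- ifelse(hit, unname(freq[subnet$nodes$node]), 0)
  subnet
}

#' Pearson correlation of subnetwork degree with mutation frequency
#'
#' @param subnet an annotated `steiner_subnetwork` (see
#'   [attach_mutation_frequency()]).
#' @param degree_from `"subnetwork"` (degree within the induced subnetwork,
#'   default) or `"network"` (degree in the full network, supplied via
#'   `network`).
#' @param network full network, required for `degree_from = "network"`.
#' @param p_method `"t"` (two-sided t transform on `n - 2` degrees of
#'   freedom) or `"permutation"`.
#' @param n_permutations resamples for the permutation p-value.
#' @param seed RNG seed for the permutation p-value.
#' @return a `pearson_result` with `r` (`NA` when either vector has zero
#'   variance), `p_value`, `n`.
#' @export
degree_frequency_correlation <- function(subnet,
                                         degree_from = c("subnetwork", "network"),
                                         network = NULL,
                                         p_method = c("t", "permutation"),
                                         n_permutations = 1000L,
                                         seed = NULL) {
  degree_from <- match.arg(degree_from)
  p_method <- match.arg(p_method)
  stopifnot(inherits(subnet, "steiner_subnetwork"))
  if (any(is.na(subnet$nodes$mutation_frequency))) {
    oncotopo_abort("subnetwork has no attached mutation frequencies", "steiner")
  }
  if (nrow(subnet$nodes) < 3L) {
    oncotopo_abort("need at least 3 annotated nodes", "steiner")
  }
  if (degree_from == "subnetwork") {
    g <- subnetwork_graph(subnet)
    deg <- igraph::degree(g)[subnet$nodes$node]
  } else {
    if (is.null(network)) {
      oncotopo_abort("supply `network` for degree_from = 'network'", "steiner")
    }
    deg <- igraph::degree(network)[subnet$nodes$node]
  }
  freq <- subnet$nodes$mutation_frequency
  if (stats::sd(deg) == 0 || stats::sd(freq) == 0) {
    return(structure(
      list(r = NA_real_, p_value = NA_real_, n = length(freq), method = p_method,
           note = "zero variance"),
      class = "pearson_result"
    ))
  }
  ct <- stats::cor.test(as.numeric(deg), freq, method = "pearson", alternative = "two.sided")
  r <- unname(ct$estimate)
  p <- unname(ct$p.value)
  if (p_method == "permutation") {
    p <- with_seed(seed, {
      robs <- abs(r)
      hits <- vapply(seq_len(n_permutations), function(i) {
        abs(stats::cor(as.numeric(deg), sample(freq))) >= robs
      }, TRUE)
      (1 + sum(hits)) / (1 + n_permutations)
    })
  }
  structure(
    list(r = r, p_value = p, n = length(freq), method = p_method, note = NULL),
    class = "pearson_result"
  )
}

#' @export
print.pearson_result <- function(x, ...) {
  if (is.na(x$r)) {
    cat(sprintf("<pearson_result> undefined r (%s), n = %d\n", x$note %||% "NA", x$n))
  } else {
    cat(sprintf("<pearson_result> r = %.3f, p = %.3g (n = %d, %s)\n",
                x$r, x$p_value, x$n, x$method))
  }
  invisible(x)
}

#' @method tidy pearson_result
#' @export
tidy.pearson_result <- function(x, ...) {
  tibble(r = x$r, p_value = x$p_value, n = x$n, method = x$method)
}

#' @method glance steiner_subnetwork
#' @export
glance.steiner_subnetwork <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes),
    n_terminal_a = sum(x$nodes$role == "terminal-A"),
    n_terminal_b = sum(x$nodes$role == "terminal-B"),
    n_linkers = sum(x$nodes$role == "linker"),
    n_edges = nrow(x$edges),
    n_tree_edges = sum(x$edges$in_tree, na.rm = TRUE)
  )
}

#' @method tidy steiner_subnetwork
#' @export
tidy.steiner_subnetwork <- function(x, ...) x$edges
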