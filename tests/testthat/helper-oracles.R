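# Independent brute-force oracles. These deliberately avoid the code paths
# (and, where feasible, the libraries) used by the implementation.

# All-shortest-path betweenness by explicit path enumeration: own BFS for
# distances, recursive backtracking over predecessor levels, fractional
# credit to interior nodes of each shortest path.
brute_betweenness <- function(g) {
  nodes <- igraph::V(g)$name
  n <- length(nodes)
  adj <- lapply(igraph::adjacent_vertices(g, nodes), as.integer)
  btw <- setNames(rep(0, n), nodes)
  if (n < 3L) {
    return(btw)
  }
  for (s in 1:(n - 1)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    while (length(frontier) > 0L) {
      nxt <- integer(0)
      for (u in frontier) {
        for (v in adj[[u]]) {
          if (is.infinite(dist[v])) {
            dist[v] <- dist[u] + 1
            nxt <- c(nxt, v)
          }
        }
      }
      frontier <- unique(nxt)
    }
    for (t in (s + 1):n) {
      if (is.infinite(dist[t])) next
      paths <- list()
      walk <- function(path) {
        u <- path[[1]]
        if (u == s) {
          paths[[length(paths) + 1L]] <<- path
          return(invisible(NULL))
        }
        for (v in adj[[u]]) {
          if (dist[v] == dist[u] - 1) walk(c(v, path))
        }
      }
      walk(t)
      interior <- unlist(lapply(paths, function(p) p[-c(1L, length(p))]))
      if (length(interior) > 0L) {
        cred <- table(interior)
        idx <- as.integer(names(cred))
        btw[idx] <- btw[idx] + as.integer(cred) / length(paths)
      }
    }
  }
  btw
}

# Two-sample K-S statistic as an explicit sup over the pooled sample points.
brute_ks_statistic <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  dmax <- 0
  for (p in pts) {
    d <- abs(mean(x <= p) - mean(y <= p))
    if (d > dmax) dmax <- d
  }
  dmax
}

# Exact node-weighted Steiner optimum by enumerating linker subsets in
# ascending total weight; feasible = terminals mutually connected in the
# induced subgraph on terminals + subset. Assumes terminals share a component
# of g. Returns the minimum linker weight.
exact_steiner_optimum <- function(g, terminals, weights) {
  linkers <- setdiff(igraph::V(g)$name, terminals)
  feasible <- function(extra) {
    h <- igraph::induced_subgraph(g, c(terminals, extra))
    comp <- igraph::components(h)$membership
    length(unique(comp[terminals])) == 1L
  }
  if (feasible(character(0))) {
    return(0)
  }
  subsets <- unlist(lapply(seq_along(linkers), function(k) {
    utils::combn(linkers, k, simplify = FALSE)
  }), recursive = FALSE)
  costs <- vapply(subsets, function(s) sum(weights[s]), 0)
  for (i in order(costs)) {
    if (feasible(subsets[[i]])) {
      return(costs[[i]])
    }
  }
  Inf
}

# quick graph builders -------------------------------------------------------

graph_from_pairs <- function(...) {
  e <- matrix(c(...), ncol = 2, byrow = TRUE)
  suppressMessages(as_interaction_network(e[, 1], e[, 2]))
}

# connected Erdős–Rényi draw (redrawn until connected)
random_connected_graph <- function(n, p, max_tries = 200L) {
  for (i in seq_len(max_tries)) {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g) && igraph::ecount(g) > 0L) {
      igraph::V(g)$name <- sprintf("N%02d", seq_len(n))
      return(g)
    }
  }
  stop("could not draw a connected graph")
}

# all labeled connected graphs on n nodes (n <= 5 stays small)
all_connected_graphs <- function(n) {
  pairs <- utils::combn(n, 2)
  m <- ncol(pairs)
  out <- list()
  for (mask in seq_len(2^m) - 1L) {
    sel <- which(bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0L)
    if (length(sel) == 0L) next
    g <- igraph::graph_from_edgelist(t(pairs[, sel, drop = FALSE]), directed = FALSE)
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
    if (igraph::is_connected(g)) {
      igraph::V(g)$name <- sprintf("N%02d", seq_len(n))
      out[[length(out) + 1L]] <- g
    }
  }
  out
}

# small synthetic study shared across tests (kept modest for speed)
toy_study <- function(seed = 11L, n_nodes = 300L) {
  synthetic_study(synthetic_spec(
    n_nodes = n_nodes, pa_m = 3L,
    set_specs = tibble::tibble(
      name = c("TSG", "OCG", "Target", "Essential"),
      size = c(30L, 30L, 40L, 40L),
      alpha = c(2, 1, 0.5, 0.5),
      rate = c(0.05, 0.01, 0.005, 0.002)
    ),
    seed = seed
  ))
}

# tiny handmade mutation table: 2 tumor types, explicit manifest
toy_mutation_table <- function() {
  records <- tibble::tibble(
    sample_id = c("s1", "s1", "s2", "s3", "s4"),
    gene = c("TP53", "TP53", "TP53", "PTEN", "KRAS"),
    tumor_type = c("BRCA", "BRCA", "BRCA", "LUAD", "LUAD"),
    variant_class = c("Missense_Mutation", "Nonsense_Mutation", "Silent", "Missense_Mutation", "Silent")
  )
  samples <- tibble::tibble(
    sample_id = c("s1", "s2", "s3", "s4", "s5"),
    tumor_type = c("BRCA", "BRCA", "LUAD", "LUAD", "BRCA")
  )
  mutation_table(records, samples)
}
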